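Q2 <- function(a, b) matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE,
                            dimnames = list(c("0", "1"), c("0", "1")))

test_that("pruning likelihood equals state-assignment enumeration", {
  tr <- tree3()
  for (i in 1:10) {
    set.seed(200 + i)
    Q <- Q2(runif(1, 0.05, 2), runif(1, 0.05, 2))
    states <- setNames(sample(c("0", "1"), 3, replace = TRUE),
                       c("A", "B", "C"))
    if (length(unique(states)) < 1) next
    expect_equal(mk_loglik(tr, states, Q), mk_loglik_enum3(Q, states),
                 tolerance = 1e-10)
  }
  # zero-rate limit: likelihood collapses onto the root prior
  Q0 <- Q2(1e-12, 1e-12)
  expect_equal(mk_loglik(tr, c(A = "0", B = "0", C = "0"), Q0), log(0.5),
               tolerance = 1e-8)
  expect_error(mk_loglik(tr, c(A = "2", B = "0", C = "0"), Q2(1, 1)),
               "state")
})

test_that("transition matrices are proper stochastic matrices", {
  set.seed(31)
  for (i in 1:5) {
    Q <- Q2(runif(1, 0.1, 3), runif(1, 0.1, 3))
    P <- moltpath:::transition_matrices(Q, c(0.01, 0.5, 2, 10))
    for (k in 1:4) {
      expect_equal(rowSums(P[, , k]), c(1, 1), tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_true(all(P[, , k] >= 0))
    }
  }
  # defective-looking rate matrix still goes through the expm fallback
  Qd <- matrix(c(-1, 1, 0, 0, -1, 1, 0, 0, 0), 3, 3, byrow = TRUE)
  P <- moltpath:::transition_matrices(Qd, 1)
  expect_equal(rowSums(P[, , 1]), rep(1, 3), tolerance = 1e-8)
})

test_that("marginal reconstruction matches brute-force conditionals", {
  tr <- tree3()
  for (i in 1:10) {
    set.seed(300 + i)
    Q <- Q2(runif(1, 0.05, 2), runif(1, 0.05, 2))
    states <- setNames(sample(c("0", "1"), 3, replace = TRUE),
                       c("A", "B", "C"))
    a <- marginal_asr(tr, states, Q)
    ref <- mk_marginals_enum3(Q, states)
    expect_equal(unname(a$prob["4", ]), ref$root, tolerance = 1e-10)
    expect_equal(unname(a$prob["5", ]), ref$mrca, tolerance = 1e-10)
    expect_equal(unname(rowSums(a$prob)), c(1, 1), tolerance = 1e-8)
  }
})

test_that("relabeling states permutes marginal probabilities exactly", {
  tr <- tree3()
  Q <- Q2(0.4, 0.9)
  states <- c(A = "0", B = "1", C = "0")
  a1 <- marginal_asr(tr, states, Q)
  # swap labels and rates
  Qs <- Q2(0.9, 0.4)
  swapped <- setNames(ifelse(states == "0", "1", "0"), names(states))
  a2 <- marginal_asr(tr, swapped, Qs)
  expect_equal(unname(a1$prob[, "0"]), unname(a2$prob[, "1"]),
               tolerance = 1e-12)
})

test_that("marginal reconstruction pins all nodes in the zero-rate limit", {
  tr <- tree3()
  a <- marginal_asr(tr, c(A = "1", B = "1", C = "1"), Q2(1e-10, 1e-10))
  expect_true(all(a$prob[, "1"] > 0.999))
})

test_that("ER fit matches an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(48, seed = 33)
  s <- simulate_mk(tr, Q2(1, 1), seed = 34)
  mine <- fit_mk(tr, s, "ER")
  ref <- phytools::fitMk(tr, s, model = "ER", pi = "equal")
  expect_equal(mine$lnL, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(mine$rates[1], ref$rates[1], tolerance = 1e-3)
  mine_ard <- fit_mk(tr, s, "ARD")
  ref_ard <- phytools::fitMk(tr, s, model = "ARD", pi = "equal")
  expect_equal(mine_ard$lnL, as.numeric(stats::logLik(ref_ard)),
               tolerance = 1e-3)
  expect_gte(mine_ard$lnL, mine$lnL - 1e-6)
})

test_that("ARD gain and loss agree under a label-symmetric configuration", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  f <- fit_mk(tr, c(A = "0", B = "1", C = "1", D = "0"), "ARD")
  expect_equal(f$Q["0", "1"], f$Q["1", "0"], tolerance = 1e-3)
})

test_that("likelihood ratio test uses the chi-square upper tail", {
  expect_equal(lrt(-10, -10, 1)$statistic, 0)
  expect_equal(lrt(-10, -10, 1)$p, 1)
  expect_equal(lrt(0, 3.841 / 2, 1)$p, 0.05, tolerance = 1e-3)
  # quadrature oracle for the tail probability
  stat <- 5.3
  tail_quad <- integrate(function(u) dchisq(u, 2), stat, Inf)$value
  expect_equal(lrt(0, stat / 2, 2)$p, tail_quad, tolerance = 1e-6)
  expect_error(lrt(-1, -2, 1), "negative")
})

test_that("transition counting follows MAP parent-child changes", {
  tr <- tree3()
  # forced case: all tips 0 -> no transitions anywhere
  a0 <- marginal_asr(tr, c(A = "0", B = "0", C = "0"), Q2(0.2, 0.2))
  ct0 <- count_transitions(tr, a0, c(A = "0", B = "0", C = "0"))
  expect_equal(ct0$gains + ct0$losses, 0)
  # enumeration oracle on random 6-tip cases
  for (i in 1:20) {
    set.seed(400 + i)
    tr6 <- simulate_yule_tree(6)
    Q <- Q2(runif(1, 0.2, 1.5), runif(1, 0.2, 1.5))
    st <- setNames(sample(c("0", "1"), 6, replace = TRUE), tr6$tip.label)
    a <- marginal_asr(tr6, st, Q)
    node_state <- c(st[tr6$tip.label], a$map)
    from <- node_state[tr6$edge[, 1]]
    to <- node_state[tr6$edge[, 2]]
    ct <- count_transitions(tr6, a, st)
    expect_equal(ct$gains, sum(from == "0" & to == "1"))
    expect_equal(ct$losses, sum(from == "1" & to == "0"))
  }
})

test_that("dependence test nests and detects perfect coupling", {
  tr <- simulate_yule_tree(50, seed = 41)
  x <- as.integer(simulate_mk(tr, Q2(1, 1), seed = 42))
  names(x) <- tr$tip.label
  if (length(unique(x)) < 2) skip("degenerate simulation")
  res <- pagel_dependence_test(tr, x, x)
  expect_gte(res$fit_dependent$lnL, res$fit_independent$lnL - 1e-6)
  expect_lt(res$fit_dependent$AIC, res$fit_independent$AIC)
  expect_error(pagel_dependence_test(tr, x, setNames(rep(1L, 50),
                                                     tr$tip.label)),
               "invariant")
})
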