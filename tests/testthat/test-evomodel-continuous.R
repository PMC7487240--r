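test_that("AICc and Akaike weights follow their closed forms", {
  expect_equal(aicc(0, 2, 48), 4 + 12 / 45)
  expect_equal(aicc(-10, 3, 48), 20 + 6 + 24 / 44)
  expect_error(aicc(0, 5, 6), "undefined")
  # AICc converges to AIC for large n
  expect_lt(abs(aicc(-10, 3, 1e5) - (20 + 6)), 0.01)
  expect_equal(aicc_weights(c(3, 3, 3)), rep(1 / 3, 3))
  w <- aicc_weights(c(100, 102, 104))
  expect_equal(sum(w), 1)
  expect_equal(w, aicc_weights(c(100, 102, 104) + 57)) # shift invariance
  expect_error(aicc_weights(c(1, NA)), "position")
})

test_that("dense Gaussian likelihood equals iid normals on a star tree", {
  star <- read_newick("(a:2,b:2,c:2,d:2);")
  x <- c(a = 0.3, b = -1, c = 2, d = 0.5)
  ll <- gaussian_phylo_loglik(vcv_matrix(star), x, sigma2 = 1.5, z0 = 0.2)
  expect_equal(ll, sum(dnorm(x, 0.2, sqrt(1.5 * 2), log = TRUE)))
  # quadratic form scales with the square of the centered data
  C <- vcv_matrix(star)
  l1 <- gaussian_phylo_loglik(C, x, 1, 0)
  l2 <- gaussian_phylo_loglik(C, 3 * x, 1, 0)
  q1 <- -2 * l1 - length(x) * log(2 * pi) - log(det(C))
  q2 <- -2 * l2 - length(x) * log(2 * pi) - log(det(C))
  expect_equal(q2, 9 * q1, tolerance = 1e-10)
})

test_that("dense and pruning likelihood evaluations agree to 1e-10", {
  for (i in 1:10) {
    n <- sample(3:6, 1)
    tr <- simulate_yule_tree(n, seed = 40 + i)
    x <- simulate_continuous(tr, "BM", seed = 60 + i)
    s2 <- runif(1, 0.3, 2)
    z0 <- rnorm(1)
    expect_equal(gaussian_phylo_loglik(vcv_matrix(tr), x[tr$tip.label],
                                       s2, z0),
                 moltpath:::bm_loglik_pruning(tr, x, s2, z0),
                 tolerance = 1e-10)
  }
})

test_that("two-tip BM fit matches the hand GLS solution", {
  # (A:1,B:1) with x = (0, 2): GLS gives z0 = 1; ML sigma2 = mean
  # squared whitened residual = 1
  tr <- read_newick("(A:1,B:1,C:1,D:1);")
  x <- c(A = 0, B = 2, C = 0, D = 2)
  fit <- fit_model(tr, x, "BM")
  expect_equal(fit$z0, 1)
  expect_equal(fit$sigma2, 1) # ML denominator n = 4
  expect_equal(fit$k, 2)
  pr <- moltpath:::profile_gaussian(vcv_matrix(read_newick("(A:1,B:1);")),
                                    c(0, 2))
  expect_equal(pr$z0, 1)
  expect_equal(pr$sigma2, 1)
})

test_that("model nesting inequalities hold on simulated data", {
  tr <- simulate_yule_tree(40, seed = 9)
  for (i in 1:5) {
    x <- simulate_continuous(tr, "BM", seed = 70 + i)
    bm <- fit_model(tr, x, "BM")
    expect_gte(fit_model(tr, x, "OU")$lnL, bm$lnL - 1e-6)
    expect_gte(fit_model(tr, x, "EB")$lnL, bm$lnL - 1e-6)
    lam <- phylo_signal_lambda(tr, x)
    expect_gte(lam$lnL, lam$lnL1 - 1e-6)
    expect_gte(lam$lnL, lam$lnL0 - 1e-6)
  }
  expect_error(fit_model(tr, setNames(rep(1, 40), tr$tip.label), "BM"),
               "invariant")
})

test_that("lambda estimate agrees with the phytools profile", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(48, seed = 13)
  x <- simulate_continuous(tr, "lambda", list(lambda = 0.6), seed = 14)
  mine <- phylo_signal_lambda(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(mine$lambda, ref$lambda, tolerance = 0.02)
  expect_equal(mine$lnL, ref$logL, tolerance = 1e-3)
})

test_that("weighted rate summary is the AICc-weighted sum across regions", {
  tr <- simulate_yule_tree(30, seed = 17)
  mkfit <- function(seed) {
    x <- simulate_continuous(tr, "BM", seed = seed)
    setNames(lapply(c("BM", "OU", "EB"), function(m) fit_model(tr, x, m)),
             c("BM", "OU", "EB"))
  }
  f1 <- mkfit(1)
  f2 <- mkfit(2)
  # hand-computed expectation
  byhand <- function(f) {
    w <- aicc_weights(vapply(f, `[[`, numeric(1), "AICc"))
    sum_rates <- vapply(f, `[[`, numeric(1), "sigma2")
    w * sum_rates
  }
  expect_equal(weighted_rate_summary(list(r1 = f1)),
               byhand(f1))
  expect_equal(weighted_rate_summary(list(r1 = f1, r2 = f2)),
               byhand(f1) + byhand(f2))
  # duplicating a region exactly doubles the summary
  expect_equal(weighted_rate_summary(list(r1 = f1, r1b = f1)),
               2 * byhand(f1))
  expect_error(weighted_rate_summary(list(r1 = f1, r2 = f2[1:2])),
               "missing model")
})

test_that("continuous ancestral states match the joint-Gaussian conditional", {
  tr <- simulate_yule_tree(4, seed = 19)
  x <- simulate_continuous(tr, "BM", seed = 20)
  fit <- fit_model(tr, x, "BM")
  a <- asr_continuous(tr, x)
  # root estimate equals the fitted root state
  expect_equal(a$estimate[a$node == 5], fit$z0)
  # brute-force conditional mean from the full joint covariance
  S <- moltpath:::full_node_vcv(tr) * fit$sigma2
  tips <- 1:4
  nodes <- 5:7
  mu <- fit$z0 + S[nodes, tips] %*% solve(S[tips, tips],
                                          x[tr$tip.label] - fit$z0)
  expect_equal(a$estimate, as.numeric(mu), tolerance = 1e-8)
  expect_true(all(a$variance >= 0))
  # (near-)constant tips give constant node estimates
  tr8 <- simulate_yule_tree(8, seed = 21)
  xc <- setNames(c(rep(3, 7), 3 + 1e-9), tr8$tip.label)
  a8 <- asr_continuous(tr8, xc)
  expect_equal(a8$estimate, rep(3, 7), tolerance = 1e-6)
})

test_that("ancestral root for a symmetric pair is the midpoint", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 0, B = 0, C = 2, D = 2)
  a <- asr_continuous(tr, x)
  expect_equal(a$estimate[a$node == 5], 1)
})
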