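test_that("Yule trees are ultrametric with the requested size and unit depth", {
  tr2 <- simulate_yule_tree(2, seed = 91)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(max(node_depths(tr2)), 1, tolerance = 1e-8)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    tr <- simulate_yule_tree(n, seed = 900 + i)
    expect_equal(length(tr$tip.label), n)
    expect_equal(tr$Nnode, n - 1) # binary tree identity
    expect_true(ultrametric_report(tr)$ultrametric)
    expect_equal(max(node_depths(tr)), 1, tolerance = 1e-8)
  }
})

test_that("Brownian simulation has the right tip moments on a star tree", {
  star <- read_newick(paste0("(", paste(sprintf("s%d:1", 1:1000),
                                        collapse = ","), ");"))
  x <- simulate_continuous(star, "BM", list(sigma2 = 2), seed = 92)
  expect_lt(abs(var(x) - 2), 0.2 * 2)
  expect_lt(abs(mean(x)), 3 * sqrt(2 / 1000) * 2)
})

test_that("strong OU pull erases covariance between distant tips", {
  tr <- simulate_yule_tree(60, seed = 93)
  V <- transform_tree(tr, "ou", 20)
  C <- vcv_matrix(tr)
  distant <- C < 0.2 & row(C) != col(C)
  stationary <- 1 / (2 * 20)
  expect_true(all(V[distant] < 0.05 * stationary))
})

test_that("lambda-zero simulations recover near-zero fitted lambda", {
  tr <- simulate_yule_tree(80, seed = 94)
  hits <- 0
  for (i in 1:20) {
    x <- simulate_continuous(tr, "lambda", list(lambda = 0),
                             seed = 940 + i)
    if (fit_model(tr, x, "lambda")$lambda <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("Mk forward simulation matches the stationary distribution", {
  # asymmetric rates on a long star tree: tips are independent draws from
  # the stationary law pi = (b, a) / (a + b)
  star <- read_newick(paste0("(", paste(sprintf("s%d:50", 1:800),
                                        collapse = ","), ");"))
  a <- 0.4; b <- 0.8
  Q <- matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  s <- simulate_mk(star, Q, root_state = "0", seed = 95)
  p1 <- mean(s == "1")
  expect_lt(abs(p1 - a / (a + b)),
            3 * sqrt(a / (a + b) * b / (a + b) / 800))
  # zero rates freeze the root state
  Q0 <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  expect_true(all(simulate_mk(star, Q0, root_state = "1", seed = 96) == "1"))
})

test_that("ER rate is recovered from forward simulations", {
  tr <- simulate_yule_tree(500, seed = 97)
  Q <- matrix(c(-1.5, 1.5, 1.5, -1.5), 2, 2,
              dimnames = list(c("0", "1"), c("0", "1")))
  est <- replicate(11, {
    s <- simulate_mk(tr, Q)
    fit_mk(tr, s, "ER")$rates[1]
  })
  expect_lt(abs(median(est) - 1.5) / 1.5, 0.3)
})

test_that("generated datasets respect their structural constraints", {
  d <- generate_warbler_like_dataset(simulation_config(n_species = 48,
                                                       seed = 98))
  expect_equal(nrow(d$predictors), 48)
  # dichromatism never exceeds molt, cell by cell
  expect_true(all(unclass(d$dichromatism) <= unclass(d$molt)))
  # region inclusion frequencies decay along the canonical order
  freq <- succession_index(d$molt)$frequency
  expect_true(all(diff(freq) <= 1e-12))
  # residents are exactly zero; migrant distances positive
  mig <- d$predictors$migration_distance
  expect_true(any(mig == 0) && any(mig > 0))
  # ordinal codes within range
  expect_true(all(d$predictors$breeding_stratum %in% 0:4))
  expect_true(all(d$predictors$nest_type %in% 0:2))
})

test_that("generation is bit-reproducible for a fixed configuration", {
  cfg <- simulation_config(n_species = 24, seed = 99)
  d1 <- generate_warbler_like_dataset(cfg)
  d2 <- generate_warbler_like_dataset(cfg)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  expect_identical(d1$predictors, d2$predictors)
  expect_identical(unclass(d1$molt), unclass(d2$molt))
  dir1 <- tempfile(); dir2 <- tempfile()
  write_fixture_dataset(dir1, cfg)
  write_fixture_dataset(dir2, cfg)
  for (f in c("tree.nwk", "scores.csv", "predictors.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("dependent-pair simulation honors zero rates and coupling", {
  tr <- simulate_yule_tree(40, seed = 101)
  pr0 <- simulate_dependent_pair(tr, rep(0, 8), root_state = "01",
                                 seed = 102)
  expect_true(all(pr0$x == 0) && all(pr0$y == 1))
})
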