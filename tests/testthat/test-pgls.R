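test_that("PGLS on a star tree reproduces ordinary least squares", {
  star <- read_newick(paste0("(", paste(sprintf("s%d:1", 1:12),
                                        collapse = ","), ");"))
  set.seed(51)
  dat <- data.frame(x = rnorm(12), row.names = star$tip.label)
  dat$y <- 1 + 0.5 * dat$x + rnorm(12)
  f <- pgls_fit(star, y ~ x, dat)
  ols <- lm(y ~ x, dat)
  sm <- summary(ols)
  expect_equal(f$coefficients, coef(ols), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(sm$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(f$F, unname(sm$fstatistic[1]), tolerance = 1e-8)
  expect_equal(f$r2, sm$r.squared, tolerance = 1e-8)
  expect_equal(f$adj_r2, sm$adj.r.squared, tolerance = 1e-8)
})

test_that("PGLS matches generalized least squares under Brownian correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule_tree(30, seed = 52)
  x <- simulate_continuous(tr, "BM", seed = 53)
  y <- 0.8 * x + simulate_continuous(tr, "BM", seed = 54) * 0.6
  dat <- data.frame(x = x, y = y, row.names = tr$tip.label)
  f <- pgls_fit(tr, y ~ x, dat)
  g <- suppressWarnings(
    nlme::gls(y ~ x, data = dat,
              correlation = ape::corBrownian(1, tr, form = ~1),
              method = "ML"))
  expect_equal(f$coefficients, coef(g), tolerance = 1e-8)
  expect_equal(f$lnL, as.numeric(stats::logLik(g)), tolerance = 1e-8)
})

test_that("exact linear relations give unit R2 and the true slope", {
  tr <- simulate_yule_tree(20, seed = 55)
  x <- simulate_continuous(tr, "BM", seed = 56)
  dat <- data.frame(x = x, y = 2 * x, row.names = tr$tip.label)
  f <- pgls_fit(tr, y ~ x, dat)
  expect_equal(unname(f$coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("degrees of freedom follow the species count", {
  d <- generate_warbler_like_dataset(simulation_config(n_species = 48,
                                                       seed = 57))
  f <- pgls_fit(d$tree, pa_extent ~ migration_distance, d$predictors)
  expect_equal(f$df, c(1, 46))
  expect_equal(f$k, 3) # slope + intercept + residual variance
})

test_that("coefficients rescale inversely with predictor scaling", {
  tr <- simulate_yule_tree(25, seed = 58)
  x <- simulate_continuous(tr, "BM", seed = 59)
  y <- x + simulate_continuous(tr, "BM", seed = 60) * 0.5
  dat <- data.frame(x = x, y = y, x10 = 10 * x, row.names = tr$tip.label)
  f1 <- pgls_fit(tr, y ~ x, dat)
  f2 <- pgls_fit(tr, y ~ x10, dat)
  expect_equal(unname(f1$coefficients["x"]),
               10 * unname(f2$coefficients["x10"]), tolerance = 1e-8)
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
})

test_that("lambda-0 equals OLS and lambda-1 equals Brownian GLS", {
  tr <- simulate_yule_tree(20, seed = 61)
  x <- simulate_continuous(tr, "BM", seed = 62)
  y <- 0.5 * x + simulate_continuous(tr, "BM", seed = 63)
  dat <- data.frame(x = x, y = y, row.names = tr$tip.label)
  f0 <- pgls_fit(tr, y ~ x, dat, correlation = "lambda-fixed", lambda = 0)
  # a star tree with matching tip depths is exactly the lambda = 0 structure
  dep <- diag(vcv_matrix(tr))
  star <- read_newick(paste0("(", paste(sprintf("%s:%.8f",
                                                tr$tip.label, dep),
                                        collapse = ","), ");"))
  fs <- pgls_fit(star, y ~ x, dat)
  expect_equal(f0$coefficients, fs$coefficients, tolerance = 1e-6)
  f1 <- pgls_fit(tr, y ~ x, dat, correlation = "lambda-fixed", lambda = 1)
  fb <- pgls_fit(tr, y ~ x, dat, correlation = "BM")
  expect_equal(f1$coefficients, fb$coefficients, tolerance = 1e-12)
  expect_equal(f1$lnL, fb$lnL, tolerance = 1e-12)
  # ML-lambda never fits worse than either boundary
  fml <- pgls_fit(tr, y ~ x, dat, correlation = "lambda-ML")
  expect_gte(fml$lnL, max(f0$lnL, f1$lnL) - 1e-6)
  expect_equal(fml$k, 4)
})

test_that("collinear designs raise a rank error naming the column", {
  tr <- simulate_yule_tree(15, seed = 64)
  x <- simulate_continuous(tr, "BM", seed = 65)
  dat <- data.frame(x = x, x2 = 2 * x, y = rnorm(15),
                    row.names = tr$tip.label)
  expect_error(pgls_fit(tr, y ~ x + x2, dat), "collinear")
})

test_that("model-set ranking orders by AICc and reweights", {
  d <- generate_warbler_like_dataset(simulation_config(n_species = 40,
                                                       seed = 66))
  tab <- rank_model_set(d$tree, "pa_extent",
                        list("migration_distance",
                             c("migration_distance", "day_length"),
                             "mass_g"),
                        d$predictors)
  expect_equal(tab$AICc, sort(tab$AICc))
  expect_equal(tab$delta_AICc[1], 0)
  expect_equal(sum(tab$aicc_weight), 1)
  # single-model set: weight 1
  tab1 <- rank_model_set(d$tree, "pa_extent", list("migration_distance"),
                         d$predictors)
  expect_equal(tab1$aicc_weight, 1)
  expect_equal(tab1$delta_AICc, 0)
})

test_that("adding a predictor never lowers the likelihood", {
  for (i in 1:10) {
    d <- generate_warbler_like_dataset(simulation_config(n_species = 30,
                                                         seed = 100 + i))
    f1 <- pgls_fit(d$tree, pa_extent ~ migration_distance, d$predictors)
    f2 <- pgls_fit(d$tree, pa_extent ~ migration_distance + mass_g,
                   d$predictors)
    expect_gte(f2$lnL, f1$lnL - 1e-8)
  }
})
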