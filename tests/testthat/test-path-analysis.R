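test_that("basis sets follow the d-sep prescription", {
  chain <- causal_dag(data.frame(from = c("X", "M"), to = c("M", "Y")))
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_equal(bs[[1]]$x, "X")
  expect_equal(bs[[1]]$y, "Y")
  expect_equal(bs[[1]]$z, "M")
  # complete DAG: nothing to test
  full <- causal_dag(data.frame(from = c("a", "a", "b"),
                                to = c("b", "c", "c")))
  expect_length(basis_set(full), 0)
  # claim count is pairs minus edges on random DAGs
  set.seed(81)
  for (i in 1:50) {
    v <- letters[1:4]
    pairs <- t(combn(v, 2))
    keep <- runif(nrow(pairs)) < 0.5
    dag <- causal_dag(data.frame(from = pairs[keep, 1],
                                 to = pairs[keep, 2]),
                      vertices = v)
    expect_length(basis_set(dag), choose(4, 2) - sum(keep))
  }
  expect_error(causal_dag(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "cyclic")
})

test_that("Fisher's C and CICc match their closed forms", {
  fc <- fisher_c(exp(-1))
  expect_equal(fc$C, 2)
  expect_equal(fc$df, 2)
  expect_equal(fc$p, exp(-1))
  expect_equal(fisher_c(c(1, 1))$C, 0)
  expect_equal(fisher_c(c(1, 1))$p, 1)
  # additivity over disjoint claim sets
  p1 <- c(0.2, 0.7)
  p2 <- c(0.05, 0.9, 0.5)
  expect_equal(fisher_c(c(p1, p2))$C, fisher_c(p1)$C + fisher_c(p2)$C)
  # chi-square tail against quadrature
  expect_equal(fc$p, integrate(function(u) dchisq(u, 2), 2, Inf)$value,
               tolerance = 1e-8)
  expect_warning(fisher_c(c(0, 0.5)), "clamped")

  expect_equal(cicc(10, 5, 48), 10 + 480 / 42)
  expect_equal(cicc(0, 0, 30), 0)
  expect_error(cicc(1, 29, 30), "undefined")
  # strictly increasing in q at fixed C, n
  vals <- vapply(1:8, function(q) cicc(5, q, 48), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("perfect dependence yields a vanishing claim p-value", {
  tr <- simulate_yule_tree(30, seed = 82)
  x <- simulate_continuous(tr, "BM", seed = 83)
  dat <- data.frame(x = x, y = x, row.names = tr$tip.label)
  cl <- test_claims(tr, dat, list(list(x = "x", y = "y", z = character(0))))
  expect_lt(cl[[1]]$p, 1e-6)
})

test_that("claim order does not change p-values", {
  d <- generate_warbler_like_dataset(simulation_config(n_species = 30,
                                                       seed = 84))
  dat <- data.frame(migration = d$predictors$migration_distance,
                    daylength = d$predictors$day_length,
                    molt = d$predictors$pa_extent,
                    row.names = rownames(d$predictors))
  c1 <- list(list(x = "migration", y = "molt", z = "daylength"),
             list(x = "daylength", y = "molt", z = character(0)))
  p_fwd <- vapply(test_claims(d$tree, dat, c1), `[[`, numeric(1), "p")
  p_rev <- vapply(test_claims(d$tree, dat, rev(c1)), `[[`, numeric(1), "p")
  expect_equal(p_fwd, rev(p_rev))
})

test_that("an edgeless-pair DAG with empty basis set scores C = 0", {
  d <- generate_warbler_like_dataset(simulation_config(n_species = 30,
                                                       seed = 85))
  dat <- data.frame(migration = d$predictors$migration_distance,
                    daylength = d$predictors$day_length,
                    row.names = rownames(d$predictors))
  full <- causal_dag(data.frame(from = "migration", to = "daylength"),
                     id = "full")
  tab <- evaluate_path_models(d$tree, dat, list(full))
  expect_equal(tab$C, 0)
  expect_equal(tab$p, 1)
  n <- 30; q <- 3
  expect_equal(tab$CICc, 2 * q * n / (n - 1 - q))
})

test_that("path-model ranking is deterministic for fixed data", {
  d <- generate_warbler_like_dataset(simulation_config(n_species = 36,
                                                       seed = 86))
  dat <- data.frame(migration = d$predictors$migration_distance,
                    daylength = d$predictors$day_length,
                    molt = d$predictors$pa_extent,
                    dichromatism = d$predictors$sd_extent,
                    stratum = d$predictors$breeding_stratum,
                    row.names = rownames(d$predictors))
  dags <- read_dag_set(system.file("extdata", "path_models.txt",
                                   package = "moltpath"))
  expect_length(dags, 12)
  t1 <- evaluate_path_models(d$tree, dat, dags)
  t2 <- evaluate_path_models(d$tree, dat, dags)
  expect_identical(t1, t2)
  expect_equal(t1$CICc, sort(t1$CICc))
  expect_true(all(is.na(t1$rank[t1$rejected])))
})
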