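# Synthetic warbler-like datasets.  The generator reproduces the causal and
# phylogenetic structure the analysis assumes: an ultrametric tree; a
# zero-inflated, phylogenetically ranked migration distance; day length
# causally downstream of migration; latent molt extent downstream of
# migration and day length with Brownian noise, discretized to region
# scores that fill in the stereotyped head-to-alula succession; and
# dichromatism downstream of molt extent and foraging stratum, constrained
# to a subset of molted regions.

#' Simulation configuration
#'
#' Default study conditions: 48 species (the empirical tree size implied by
#' F with 1 and 46 degrees of freedom), tree depth rescaled to 1, and path
#' coefficients under which day length sits between migration and molt,
#' and molt extent plus foraging stratum drive dichromatism.  The default
#' causal graph has no direct migration -> molt edge: molt responds to
#' migration only through day length.
#'
#' @param n_species Number of tips (>= 4).
#' @param seed Integer seed recorded in all outputs.
#' @param birth_rate Yule speciation rate.
#' @param zero_inflation Fraction of species forced to zero migration
#'   distance (residents).
#' @param mig_meanlog,mig_sdlog Lognormal parameters for migrant distances
#'   (degrees latitude).
#' @param coef_mig_daylength,coef_mig_molt,coef_daylength_molt,
#'   coef_molt_dichromatism,coef_stratum_dichromatism Path coefficients on
#'   standardized scales.
#' @param sd_daylength,sd_molt Brownian noise scales (tip SD at depth 1) for
#'   day length and latent molt extent.
#' @param sd_dichromatism Independent noise SD for the dichromatism latent.
#' @param regions Ordered region list for score discretization.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 48, seed = 1, birth_rate = 1,
                              zero_inflation = 1 / 3,
                              mig_meanlog = log(20), mig_sdlog = 0.6,
                              coef_mig_daylength = 0.8,
                              coef_mig_molt = 0,
                              coef_daylength_molt = 0.6,
                              coef_molt_dichromatism = 0.7,
                              coef_stratum_dichromatism = 0.45,
                              sd_daylength = 0.4, sd_molt = 0.6,
                              sd_dichromatism = 0.55,
                              regions = canonical_regions()) {
  cfg <- as.list(environment())
  if (cfg$n_species < 4) stop("n_species must be >= 4")
  sds <- c(cfg$sd_daylength, cfg$sd_molt, cfg$sd_dichromatism)
  if (any(sds < 0)) stop("noise SDs must be >= 0")
  coefs <- c(cfg$coef_mig_daylength, cfg$coef_mig_molt,
             cfg$coef_daylength_molt, cfg$coef_molt_dichromatism,
             cfg$coef_stratum_dichromatism)
  if (any(!is.finite(coefs))) stop("path coefficients must be finite")
  if (cfg$zero_inflation < 0 || cfg$zero_inflation >= 1)
    stop("zero_inflation must be in [0, 1)")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth simulation conditioned on the tip count, with the tree depth
#' rescaled to 1.
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate (affects relative node heights only,
#'   after rescaling).
#' @param seed Optional integer seed.
#' @return A `phylo` object with tips `t1 ... tn`.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 2) stop("n must be >= 2")
  # node records: start time of the branch leading to the node
  start <- c(NA_real_, 0, 0) # 1 = root, 2:3 its children
  parent <- c(NA_integer_, 1L, 1L)
  active <- c(2L, 3L)
  t_now <- 0
  while (length(active) < n) {
    t_now <- t_now + rexp(1, birth_rate * length(active))
    i <- active[sample.int(length(active), 1)]
    id1 <- length(start) + 1L; id2 <- id1 + 1L
    start <- c(start, t_now, t_now)
    parent <- c(parent, i, i)
    active <- c(setdiff(active, i), id1, id2)
  }
  t_end <- t_now + rexp(1, birth_rate * n)
  # assemble newick recursively
  kids <- split(seq_along(parent), parent)
  tip_counter <- 0L
  build <- function(id) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch)) {
      tip_counter <<- tip_counter + 1L
      return(sprintf("t%d:%.10f", tip_counter, (t_end - start[id]) / t_end))
    }
    len <- if (id == 1L) 0 else (start[ch[1]] - start[id]) / t_end
    sprintf("(%s,%s):%.10f", build(ch[1]), build(ch[2]), len)
  }
  txt <- paste0(build(1L), ";")
  tr <- ape::read.tree(text = txt)
  validate_phylo(tr)
  tr
}

#' Simulate a continuous character on a tree
#'
#' Draws tip values from `Normal(z0 * 1, sigma2 * V(model, params))` with
#' `V` the BM, OU, EB or lambda covariance from [transform_tree()].
#'
#' @param tree A `phylo` object.
#' @param model `"BM"`, `"OU"`, `"EB"` or `"lambda"`.
#' @param params List with `sigma2` (default 1), `z0` (default 0), and the
#'   structural parameter (`alpha`, `r` or `lambda`) where relevant.
#' @param seed Optional integer seed.
#' @return Named per-tip values.
#' @export
simulate_continuous <- function(tree, model = "BM", params = list(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma2 <- params$sigma2 %||% 1
  z0 <- params$z0 %||% 0
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  V <- switch(model,
    BM = vcv_matrix(tree),
    OU = transform_tree(tree, "ou", params$alpha %||% 1),
    EB = transform_tree(tree, "eb", params$r %||% -1),
    lambda = transform_tree(tree, "lambda", params$lambda %||% 1),
    stop("unknown model"))
  L <- t(chol(sigma2 * V + diag(1e-12, nrow(V))))
  x <- z0 + as.numeric(L %*% rnorm(nrow(V)))
  setNames(x, rownames(V))
}

#' Simulate a discrete character under an Mk model
#'
#' Forward simulation along branches with exponential waiting times.
#'
#' @param tree A `phylo` object.
#' @param Q Rate matrix with state names as dimnames.
#' @param root_state Root state name, or `NULL` to draw from a flat prior.
#' @param seed Optional integer seed.
#' @return Named per-tip states (character).
#' @export
simulate_mk <- function(tree, Q, root_state = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_Q(Q)
  states <- rownames(Q) %||% as.character(seq_len(nrow(Q)) - 1L)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  node_state <- integer(nn)
  root <- n + 1L
  node_state[root] <- if (is.null(root_state))
    sample.int(length(states), 1) else match(root_state, states)
  pre <- reorder_edges_preorder(tree)
  for (i in pre) {
    s <- node_state[tree$edge[i, 1]]
    t_left <- tree$edge.length[i]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- rexp(1, rate)
      if (w >= t_left) break
      t_left <- t_left - w
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(length(states), 1, prob = probs)
    }
    node_state[tree$edge[i, 2]] <- s
  }
  setNames(states[node_state[seq_len(n)]], tree$tip.label)
}

#' Simulate a correlated pair of binary characters
#'
#' Forward simulation of the 4-state composite chain of
#' [pagel_dependence_test()], returning the two marginal binary traits.
#'
#' @param tree A `phylo` object.
#' @param rates8 The 8 dependent-model rates, in the order
#'   `q00_01, q00_10, q01_00, q01_11, q10_00, q10_11, q11_01, q11_10`
#'   (state labels: trait x then trait y).
#' @param root_state Composite root state (`"00"`, `"01"`, `"10"`, `"11"`),
#'   or `NULL` for a flat draw.
#' @param seed Optional integer seed.
#' @return List with named 0/1 vectors `x` and `y`.
#' @export
simulate_dependent_pair <- function(tree, rates8, root_state = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- pagel_Q_dependent(rates8)
  combo <- simulate_mk(tree, Q, root_state = root_state)
  list(x = setNames(as.integer(substr(combo, 1, 1)), names(combo)),
       y = setNames(as.integer(substr(combo, 2, 2)), names(combo)))
}

# map a latent vector to half-integer extents in [0, n_regions] via its
# normal score, preserving rank order
latent_to_extent <- function(latent, n_regions) {
  z <- (latent - mean(latent)) / sd(latent)
  round(2 * n_regions * pnorm(z)) / 2
}

# fill an extent along the succession order: full scores first, a half
# score at the moving front
extent_to_scores <- function(ext, regions) {
  m <- matrix(0, length(ext), length(regions),
              dimnames = list(names(ext), regions))
  for (i in seq_along(ext)) {
    full <- floor(ext[i])
    if (full > 0) m[i, seq_len(min(full, length(regions)))] <- 1
    if (ext[i] - full > 0 && full < length(regions)) m[i, full + 1] <- 0.5
  }
  m
}

#' Generate a complete warbler-like dataset
#'
#' Produces a tree, molt and dichromatism region-score matrices, and a
#' predictor table with the generating causal structure:
#' migration -> day length -> molt extent -> dichromatism extent, with
#' foraging stratum a second parent of dichromatism, Brownian noise on the
#' phylogeny for day length and molt, and region scores filling the
#' head-to-alula succession.  Dichromatism scores never exceed molt scores
#' in any region.
#'
#' @param config A [simulation_config()].
#' @return List: `tree`, `molt` and `dichromatism` (`region_scores`),
#'   `predictors` (data frame with species rownames), `latent` (the
#'   generating latent variables), `config`.
#' @export
generate_warbler_like_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    stop("config must come from simulation_config()")
  set.seed(config$seed)
  tree <- simulate_yule_tree(config$n_species, config$birth_rate)
  sp <- tree$tip.label
  n <- length(sp)
  nr <- length(config$regions)
  scale01 <- function(v) (v - mean(v)) / sd(v)

  # zero-inflated migration distance with BM-correlated ranking
  mig_latent <- simulate_continuous(tree, "BM")
  rk <- rank(mig_latent, ties.method = "first")
  n_zero <- floor(config$zero_inflation * n)
  migration <- numeric(n)
  migrants <- rk > n_zero
  qq <- (rank(mig_latent[migrants], ties.method = "first") - 0.5) /
    sum(migrants)
  migration[migrants] <- qlnorm(qq, config$mig_meanlog, config$mig_sdlog)
  names(migration) <- sp
  mig_s <- scale01(migration)

  day_length <- 12 + config$coef_mig_daylength * mig_s +
    simulate_continuous(tree, "BM", list(sigma2 = config$sd_daylength^2))
  dl_s <- scale01(day_length)

  stratum <- sample(0:4, n, replace = TRUE)
  names(stratum) <- sp
  str_s <- scale01(stratum)

  molt_latent <- config$coef_mig_molt * mig_s +
    config$coef_daylength_molt * dl_s +
    simulate_continuous(tree, "BM", list(sigma2 = config$sd_molt^2))
  molt_ext <- latent_to_extent(molt_latent, nr)
  molt_scores <- extent_to_scores(molt_ext, config$regions)

  dich_latent <- config$coef_molt_dichromatism * scale01(molt_ext) +
    config$coef_stratum_dichromatism * str_s +
    rnorm(n, 0, config$sd_dichromatism)
  names(dich_latent) <- sp
  dich_ext_target <- latent_to_extent(dich_latent, nr)
  dich_scores <- pmin(extent_to_scores(dich_ext_target, config$regions),
                      molt_scores)

  molt <- region_scores(molt_scores, "molt")
  dich <- region_scores(dich_scores, "dichromatism")

  predictors <- data.frame(
    migration_distance = migration,
    day_length = day_length,
    breeding_stratum = stratum,
    winter_stratum = ordinal_codes(
      pmin(4, pmax(0, stratum + sample(c(-1, 0, 0, 1), n, replace = TRUE))),
      "stratum"),
    breeding_habitat = sample(0:6, n, replace = TRUE),
    nest_type = sample(0:2, n, replace = TRUE, prob = c(0.1, 0.2, 0.7)),
    mass_g = round(exp(rnorm(n, log(10), 0.25)), 2),
    pa_extent = extent(molt),
    pa_presence = presence(molt),
    sd_extent = extent(dich),
    sd_presence = presence(dich),
    row.names = sp)

  list(tree = tree, molt = molt, dichromatism = dich,
       predictors = predictors,
       latent = data.frame(mig_latent = mig_latent,
                           molt_latent = molt_latent,
                           dich_latent = dich_latent, row.names = sp),
       config = config)
}

#' Write a deterministic fixture dataset
#'
#' Emits the Newick tree, the combined score CSV and the predictor CSV the
#' pipeline consumes, for use in tests and examples.
#'
#' @param dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @return Invisible named vector of the three file paths.
#' @export
write_fixture_dataset <- function(dir, config = simulation_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- generate_warbler_like_dataset(config)
  tree_path <- file.path(dir, "tree.nwk")
  scores_path <- file.path(dir, "scores.csv")
  pred_path <- file.path(dir, "predictors.csv")
  writeLines(write_newick(d$tree), tree_path)
  write_region_scores(d$molt, d$dichromatism, scores_path)
  write.csv(cbind(species = rownames(d$predictors), d$predictors),
            pred_path, row.names = FALSE)
  invisible(c(tree = tree_path, scores = scores_path,
              predictors = pred_path))
}
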