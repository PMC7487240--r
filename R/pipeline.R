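# End-to-end orchestration: read tree + trait + predictor tables, prune to
# the common species set, and run model selection, phylogenetic signal,
# discrete-model tests, ancestral reconstruction, PGLS model ranking,
# per-region phylogenetic ANOVA and path-model evaluation, writing one CSV
# per stage plus a run manifest.  All randomness is seeded and logged, so
# re-running an identical configuration is bit-identical.

#' Pipeline configuration
#'
#' @param tree Path to a Newick file.
#' @param scores Path to the combined region-score CSV (`pa_*`/`sd_*`
#'   columns; see [read_region_scores()]).
#' @param predictors Path to the predictor CSV (column `species`).
#' @param dag_file Path to a DAG-set file ([read_dag_set()]); defaults to
#'   the candidate set shipped with the package.
#' @param out_dir Output directory.
#' @param correlation PGLS correlation structure (`"BM"`, `"lambda-ML"`).
#' @param n_sim Phylogenetic-ANOVA null simulations.
#' @param seed Integer master seed.
#' @param model_sets Named list (`pa_extent`, `sd_extent`) of lists of
#'   predictor subsets for [rank_model_set()]; a compact default mirroring
#'   the molt / dichromatism model families is used when `NULL`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tree, scores, predictors, out_dir,
                            dag_file = system.file("extdata",
                                                   "path_models.txt",
                                                   package = "moltpath"),
                            correlation = "BM", n_sim = 1000, seed = 1,
                            model_sets = NULL) {
  for (f in c(tree, scores, predictors, dag_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  if (seed != round(seed)) stop("seed must be an integer")
  if (is.null(model_sets)) model_sets <- default_model_sets()
  structure(list(tree = tree, scores = scores, predictors = predictors,
                 dag_file = dag_file, out_dir = out_dir,
                 correlation = correlation, n_sim = n_sim,
                 seed = as.integer(seed), model_sets = model_sets),
            class = "pipeline_config")
}

default_model_sets <- function() {
  list(
    pa_extent = list(
      c("migration_distance", "day_length"),
      "migration_distance",
      "day_length",
      c("day_length", "breeding_stratum"),
      "breeding_stratum",
      "mass_g"),
    sd_extent = list(
      c("pa_extent", "winter_stratum"),
      c("pa_extent", "breeding_stratum"),
      "pa_extent",
      c("migration_distance", "breeding_stratum"),
      "migration_distance",
      "breeding_stratum"))
}

#' Load a YAML pipeline configuration
#'
#' Thin wrapper: reads the file with the `yaml` package and passes the
#' fields to [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full comparative analysis
#'
#' Stages: (1) continuous model selection (BM/OU/EB) with AICc weights for
#' extent and presence of molt and dichromatism plus per-region weighted
#' rate summary; (2) phylogenetic signal (Pagel's lambda); (3) ER/ARD
#' likelihood-ratio tests and Pagel's dependence test of molt presence on
#' long-distance migration; (4) discrete ancestral reconstruction per
#' region; (5) AICc-ranked PGLS model sets for molt and dichromatism
#' extent; (6) per-region phylogenetic ANOVA of migration distance on molt
#' presence with Holm correction; (7) path-model ranking.  Writes one CSV
#' per stage and `manifest.txt` into `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of all stage results.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(...) message(sprintf(...))

  tree <- read_newick(file = config$tree)
  molt <- read_region_scores(config$scores, "pa", "molt")
  dich <- read_region_scores(config$scores, "sd", "dichromatism")
  pred <- read.csv(config$predictors)
  rownames(pred) <- pred$species

  pruned <- prune_to_common(tree, intersect(rownames(molt), pred$species))
  tree <- pruned$tree
  sp <- pruned$species
  molt <- region_scores(unclass(molt)[sp, , drop = FALSE], "molt")
  dich <- region_scores(unclass(dich)[sp, , drop = FALSE], "dichromatism")
  pred <- pred[sp, , drop = FALSE]
  umet <- ultrametric_report(tree)
  if (!umet$ultrametric)
    warning("tree is not ultrametric (depth range ",
            signif(umet$depth_range, 3), ")")
  logf("pruned to %d species (%d dropped from tree, %d from tables)",
       length(sp), length(pruned$dropped_from_tree),
       length(pruned$dropped_from_data))

  traits <- list(pa_extent = extent(molt), pa_presence = presence(molt),
                 sd_extent = extent(dich), sd_presence = presence(dich))

  # (1) continuous model selection (invariant characters skipped with a note)
  msel <- do.call(rbind, lapply(names(traits), function(tn) {
    x <- traits[[tn]]
    if (var(x) == 0) {
      logf("note: `%s` is invariant; model selection skipped", tn)
      return(NULL)
    }
    if (all(x %in% c(0, 1)))
      logf("note: 0/1 character `%s` passed to Gaussian fits", tn)
    fits <- lapply(c("BM", "OU", "EB"), function(m) fit_model(tree, x, m))
    w <- aicc_weights(vapply(fits, `[[`, numeric(1), "AICc"))
    data.frame(character = tn,
               model = c("BM", "OU", "EB"),
               sigma2 = vapply(fits, `[[`, numeric(1), "sigma2"),
               lnL = vapply(fits, `[[`, numeric(1), "lnL"),
               k = vapply(fits, `[[`, numeric(1), "k"),
               AICc = vapply(fits, `[[`, numeric(1), "AICc"),
               aicc_weight = w,
               binary_response = all(x %in% c(0, 1)))
  }))
  write.csv(msel, file.path(config$out_dir, "model_selection.csv"),
            row.names = FALSE)

  # per-region weighted rate summary (regions with variation only)
  region_fits <- list()
  for (r in colnames(molt)) {
    x <- unclass(molt)[, r]
    names(x) <- sp
    if (var(x) == 0) next
    region_fits[[r]] <- setNames(
      lapply(c("BM", "OU", "EB"), function(m) fit_model(tree, x, m)),
      c("BM", "OU", "EB"))
  }
  if (length(region_fits)) {
    wr <- weighted_rate_summary(region_fits)
    write.csv(data.frame(model = names(wr), summed_weighted_rate = wr),
              file.path(config$out_dir, "weighted_rates.csv"),
              row.names = FALSE)
  }

  # (2) phylogenetic signal
  sig <- do.call(rbind, lapply(names(traits), function(tn) {
    if (var(traits[[tn]]) == 0) return(NULL)
    s <- phylo_signal_lambda(tree, traits[[tn]])
    data.frame(character = tn, lambda = s$lambda, lnL = s$lnL,
               lnL_lambda0 = s$lnL0, lnL_lambda1 = s$lnL1)
  }))
  write.csv(sig, file.path(config$out_dir, "phylo_signal.csv"),
            row.names = FALSE)

  # (3) discrete models: ER vs ARD, Pagel dependence
  disc <- do.call(rbind, lapply(c("pa_presence", "sd_presence"),
                                function(tn) {
    x <- traits[[tn]]
    if (length(unique(x)) < 2) return(NULL)
    er <- fit_mk(tree, x, "ER")
    ard <- fit_mk(tree, x, "ARD")
    lt <- lrt(er$lnL, ard$lnL, df = ard$k - er$k)
    data.frame(character = tn, lnL_ER = er$lnL, lnL_ARD = ard$lnL,
               rate_ER = er$rates[1],
               gain_ARD = ard$Q["0", "1"], loss_ARD = ard$Q["1", "0"],
               lrt_stat = lt$statistic, lrt_p = lt$p)
  }))
  write.csv(disc, file.path(config$out_dir, "discrete_tests.csv"),
            row.names = FALSE)

  long_migration <- as.integer(pred$migration_distance >
                                 median(pred$migration_distance))
  names(long_migration) <- sp
  pagel <- tryCatch(
    pagel_dependence_test(tree, long_migration, traits$pa_presence),
    error = function(e) NULL)
  if (!is.null(pagel)) {
    write.csv(data.frame(AIC_dependent = pagel$fit_dependent$AIC,
                         AIC_independent = pagel$fit_independent$AIC,
                         lrt_stat = pagel$lrt$statistic,
                         lrt_p = pagel$lrt$p,
                         t(pagel$rates_dependent)),
              file.path(config$out_dir, "pagel_dependence.csv"),
              row.names = FALSE)
  }

  # (4) discrete ASR per region
  asr_rows <- list()
  for (r in colnames(molt)) {
    x <- presence(molt, by_region = TRUE)[, r]
    names(x) <- sp
    if (length(unique(x)) < 2) next
    er <- fit_mk(tree, x, "ER")
    a <- marginal_asr(tree, x, er$Q)
    asr_rows[[r]] <- data.frame(region = r,
                                node = rownames(a$prob),
                                p_absent = a$prob[, 1],
                                p_present = a$prob[, 2],
                                map = a$map)
  }
  if (length(asr_rows))
    write.csv(do.call(rbind, asr_rows),
              file.path(config$out_dir, "asr_regions.csv"),
              row.names = FALSE)

  # (5) PGLS model ranking
  dat <- cbind(pred, pa_extent = traits$pa_extent,
               sd_extent = traits$sd_extent)
  dat <- dat[, !duplicated(names(dat))]
  ranks <- lapply(names(config$model_sets), function(resp) {
    tab <- rank_model_set(tree, resp, config$model_sets[[resp]], dat,
                          correlation = config$correlation)
    tab$response <- resp
    tab
  })
  write.csv(do.call(rbind, ranks),
            file.path(config$out_dir, "pgls_ranking.csv"),
            row.names = FALSE)

  # (6) per-region phylogenetic ANOVA
  mig <- pred$migration_distance
  names(mig) <- sp
  anova_tab <- phylo_anova_regions(tree, mig,
                                   presence(molt, by_region = TRUE),
                                   n_sim = config$n_sim,
                                   seed = config$seed)
  write.csv(anova_tab, file.path(config$out_dir, "phylo_anova.csv"),
            row.names = FALSE)

  # (7) path analysis
  dags <- read_dag_set(config$dag_file)
  path_dat <- data.frame(migration = mig,
                         daylength = pred$day_length,
                         molt = traits$pa_extent,
                         dichromatism = traits$sd_extent,
                         stratum = pred$breeding_stratum,
                         row.names = sp)
  path_tab <- evaluate_path_models(tree, path_dat, dags,
                                   correlation = config$correlation)
  write.csv(path_tab, file.path(config$out_dir, "path_models.csv"),
            row.names = FALSE)

  manifest <- c(
    sprintf("moltpath %s", as.character(utils::packageVersion("moltpath"))),
    sprintf("seed: %d", config$seed),
    sprintf("n_species: %d", length(sp)),
    sprintf("correlation: %s", config$correlation),
    sprintf("n_sim: %d", config$n_sim),
    sprintf("ultrametric: %s", umet$ultrametric),
    sprintf("dropped_from_tree: %s",
            paste(pruned$dropped_from_tree, collapse = " ")),
    sprintf("dropped_from_data: %s",
            paste(pruned$dropped_from_data, collapse = " ")),
    sprintf("inputs: %s %s %s", config$tree, config$scores,
            config$predictors))
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  logf("pipeline finished in %.1f s",
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(model_selection = msel, signal = sig, discrete = disc,
                 pagel = pagel, pgls = ranks, anova = anova_tab,
                 path = path_tab, manifest = manifest))
}
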