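# Simulation-based phylogenetic ANOVA: the observed one-way F statistic is
# referred to a null distribution of F values computed from Brownian-motion
# simulations on the tree, so the test accounts for phylogenetic
# non-independence of species values.

#' Phylogenetic ANOVA by Brownian-motion simulation
#'
#' The observed F is the standard one-way ANOVA F of `y` on `groups`.  The
#' null distribution is built by simulating `n_sim` Brownian datasets on the
#' tree (rate estimated from `y` by [fit_model()]), recomputing F against
#' the fixed group labels each time; the p-value is
#' `(1 + #\{F_sim >= F_obs\}) / (1 + n_sim)` and is therefore bounded below
#' by `1/(n_sim + 1)`.  A zero within-group sum of squares gives infinite F,
#' flagged `degenerate`.
#'
#' @param tree A `phylo` object.
#' @param y Named continuous per-tip values.
#' @param groups Named per-tip group labels (>= 2 groups of >= 2 members).
#' @param n_sim Number of null simulations (>= 100; default 1000).
#' @param seed Integer seed, recorded in the result.
#' @return A `phylo_anova_result` list: `F`, `p`, `n_sim`, `seed`,
#'   `degenerate`, `sigma2` (null simulation rate).
#' @export
phylo_anova <- function(tree, y, groups, n_sim = 1000, seed = 1) {
  validate_phylo(tree)
  y <- align_tip_values(tree, y)
  groups <- align_tip_states(tree, as.character(groups))
  if (n_sim < 100) stop("n_sim must be >= 100")
  tabg <- table(groups)
  if (length(tabg) < 2) stop("need at least 2 groups")
  if (any(tabg < 2)) stop("group(s) with fewer than 2 members: ",
                          paste(names(tabg)[tabg < 2], collapse = ", "))
  if (var(y) == 0) stop("constant y")
  g <- factor(groups)
  Fobs <- oneway_F(y, g)
  fit <- fit_model(tree, y, "BM")
  C <- vcv_matrix(tree)
  L <- t(chol(C))
  set.seed(seed)
  Z <- matrix(rnorm(length(y) * n_sim), length(y), n_sim)
  sims <- sqrt(fit$sigma2) * (L %*% Z)
  Fsim <- oneway_F_matrix(sims, g)
  degenerate <- !is.finite(Fobs)
  p <- (1 + sum(Fsim >= Fobs)) / (1 + n_sim)
  structure(list(F = Fobs, p = p, n_sim = n_sim, seed = seed,
                 degenerate = degenerate, sigma2 = fit$sigma2),
            class = "phylo_anova_result")
}

# classical one-way F; Inf when the within-group SS is zero
oneway_F <- function(y, g) {
  n <- length(y)
  k <- nlevels(g)
  gm <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# vectorized over columns of a simulation matrix
oneway_F_matrix <- function(Y, g) {
  n <- nrow(Y)
  k <- nlevels(g)
  G <- model.matrix(~ g - 1)
  cnt <- colSums(G)
  gm <- (t(G) %*% Y) / cnt # k x nsim group means
  colm <- colMeans(Y)
  ssb <- colSums(cnt * (gm - rep(colm, each = k))^2)
  sst <- colSums((Y - rep(colm, each = n))^2)
  ssw <- sst - ssb
  ifelse(ssw <= 0, Inf, (ssb / (k - 1)) / (ssw / (n - k)))
}

#' Per-region phylogenetic ANOVA with Holm correction
#'
#' Runs [phylo_anova()] for each feather region — response `y` (typically
#' migration distance) against presence/absence of molt in the region — and
#' applies Holm's sequential Bonferroni across regions.  Regions where the
#' grouping is invariant or a group has fewer than 2 members are reported
#' with NA.
#'
#' @param tree A `phylo` object.
#' @param y Named continuous response per tip.
#' @param presence_matrix 0/1 matrix, species x regions (see
#'   [presence()] with `by_region = TRUE`).
#' @param n_sim,seed Passed to [phylo_anova()].
#' @return Data frame: region, F, p, p_holm, n_sim, seed.
#' @export
phylo_anova_regions <- function(tree, y, presence_matrix, n_sim = 1000,
                                seed = 1) {
  regions <- colnames(presence_matrix)
  res <- lapply(seq_along(regions), function(i) {
    grp <- presence_matrix[, i]
    names(grp) <- rownames(presence_matrix)
    tryCatch({
      a <- phylo_anova(tree, y, grp, n_sim = n_sim, seed = seed + i)
      c(F = a$F, p = a$p)
    }, error = function(e) c(F = NA_real_, p = NA_real_))
  })
  tab <- data.frame(region = regions,
                    F = vapply(res, `[[`, numeric(1), "F"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  tab$p_holm <- NA_real_
  ok <- !is.na(tab$p)
  if (any(ok)) tab$p_holm[ok] <- holm_adjust(tab$p[ok])
  tab$n_sim <- n_sim
  tab$seed <- seed
  tab
}

#' Holm's sequential Bonferroni adjustment
#'
#' Step-down adjustment: sort p-values ascending, multiply the i-th by
#' `(m - i + 1)`, enforce monotonicity, cap at 1, and return in the
#' original order.  Delegates to `stats::p.adjust(method = "holm")` after
#' validating the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  p.adjust(pvalues, method = "holm")
}
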