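# Maximum-likelihood fitting of Gaussian models of continuous trait
# evolution (Brownian motion, Ornstein-Uhlenbeck, early burst, Pagel's
# lambda).  The rate sigma^2 and root state z0 are profiled in closed form
# by GLS for every candidate structural parameter; the structural parameter
# (alpha, r or lambda) is then found by bounded one-dimensional search.
# sigma^2 uses the ML (n) denominator so AICc comparisons line up across
# models.

#' Log-likelihood of tip data under a Gaussian phylogenetic model
#'
#' Density of `x ~ Normal(z0 * 1, sigma2 * C)` evaluated by dense Cholesky
#' factorization.
#'
#' @param C Phylogenetic covariance matrix (tips aligned with `x`).
#' @param x Per-tip trait values.
#' @param sigma2 Rate (> 0).
#' @param z0 Root state.
#' @return The log-likelihood.
#' @export
gaussian_phylo_loglik <- function(C, x, sigma2, z0) {
  n <- length(x)
  if (!is.matrix(C) || nrow(C) != n) stop("C does not match x")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  L <- tryCatch(chol(sigma2 * C),
                error = function(e) stop("sigma2 * C is singular; ",
                                         "consider PSD repair", call. = FALSE))
  r <- x - z0
  u <- backsolve(L, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(u^2))
}

# Felsenstein peeling evaluation of the Brownian likelihood: an independent
# algorithm used to cross-check the dense-matrix path.
bm_loglik_pruning <- function(tree, x, sigma2, z0) {
  n <- length(tree$tip.label)
  x <- x[tree$tip.label]
  nn <- n + tree$Nnode
  mu <- numeric(nn); vv <- numeric(nn) # conditional mean & extra variance
  mu[seq_len(n)] <- x
  lnL <- 0
  elen <- tree$edge.length
  post <- reorder_edges_postorder(tree)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  done <- logical(nn); done[seq_len(n)] <- TRUE
  for (i in post) {
    p <- tree$edge[i, 1]
    if (done[p]) next
    kid_edges <- children[[as.character(p)]]
    # peel children pairwise (works for multifurcations too)
    ms <- mu[tree$edge[kid_edges, 2]]
    vs <- vv[tree$edge[kid_edges, 2]] + elen[kid_edges] * sigma2
    m <- ms[1]; v <- vs[1]
    for (k in seq_along(ms)[-1]) {
      lnL <- lnL - 0.5 * (log(2 * pi * (v + vs[k])) +
                            (m - ms[k])^2 / (v + vs[k]))
      m <- (m * vs[k] + ms[k] * v) / (v + vs[k])
      v <- v * vs[k] / (v + vs[k])
    }
    mu[p] <- m; vv[p] <- v
    done[p] <- TRUE
  }
  root <- length(tree$tip.label) + 1L
  lnL - 0.5 * (log(2 * pi * vv[root]) + (mu[root] - z0)^2 / vv[root])
}

# GLS profile of (z0, sigma2) given a correlation-scale matrix V;
# returns the profiled log-likelihood and estimates.
profile_gaussian <- function(V, x) {
  n <- length(x)
  L <- chol(V)
  one <- rep(1, n)
  iV1 <- backsolve(L, backsolve(L, one, transpose = TRUE))
  iVx <- backsolve(L, backsolve(L, x, transpose = TRUE))
  z0 <- sum(iVx) / sum(iV1)
  r <- x - z0
  q <- sum(r * backsolve(L, backsolve(L, r, transpose = TRUE)))
  sigma2 <- q / n
  logdet <- 2 * sum(log(diag(L)))
  lnL <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(z0 = z0, sigma2 = sigma2, lnL = lnL)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param lnL Log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from information-criterion values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = IC_i - min(IC)`.  Invariant to adding a constant to all
#' values.
#'
#' @param values AICc (or AIC) values.
#' @return Weights summing to 1, in input order.
#' @export
aicc_weights <- function(values) {
  if (any(is.na(values)))
    stop("NaN/NA in information-criterion values at position(s) ",
         paste(which(is.na(values)), collapse = ", "))
  d <- values - min(values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit a Gaussian model of continuous trait evolution
#'
#' Fits one of Brownian motion (`BM`), single-optimum Ornstein-Uhlenbeck
#' (`OU`), early burst (`EB`) or Pagel's lambda (`lambda`) by maximum
#' likelihood.  The structural parameter is optimized by bounded search over
#' five subintervals of its range (a deterministic multi-start); the
#' boundary value reproducing Brownian motion is always evaluated, so the
#' nested-model inequality `lnL(OU|EB|lambda) >= lnL(BM)` holds up to
#' optimizer tolerance.
#'
#' Default parameter ranges, with `depth` the maximum root-to-tip length:
#' `alpha` in `[0, 50/depth]`, `r` in `[-10/depth, 0]`, `lambda` in
#' `[0, lambda_max]` (PSD-preserving).  Binary presence characters may be
#' passed; the fit is then flagged `binary_response = TRUE` in the result.
#'
#' @param tree A `phylo` object.
#' @param x Named per-tip values (names matched to tip labels).
#' @param model `"BM"`, `"OU"`, `"EB"` or `"lambda"`.
#' @param bounds Optional `c(lower, upper)` override for the structural
#'   parameter.
#' @return A `continuous_fit` list: model, sigma2, z0, structural parameter
#'   (alpha / r / lambda where relevant), lnL, k, n, AICc.
#' @export
fit_model <- function(tree, x, model = c("BM", "OU", "EB", "lambda"),
                      bounds = NULL) {
  model <- match.arg(model)
  validate_phylo(tree)
  x <- align_tip_values(tree, x)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips")
  if (var(x) == 0) stop("invariant character: trait has zero variance")
  C <- vcv_matrix(tree)
  depth <- max(diag(C))
  k <- if (model == "BM") 2L else 3L
  if (n <= k + 1) stop("AICc undefined: n too small for model")

  if (model == "BM") {
    pr <- profile_gaussian(C, x)
    par <- NULL
  } else {
    Vfun <- switch(model,
      OU = function(a) ou_cov(C, a),
      EB = function(r) transform_tree(tree, "eb", r),
      lambda = function(l) { V <- C * l; diag(V) <- diag(C); V })
    rng <- if (!is.null(bounds)) bounds else switch(model,
      OU = c(0, 50 / depth),
      EB = c(-10 / depth, 0),
      lambda = c(0, min(lambda_max(C), 1.5)))
    obj <- function(p) profile_gaussian(Vfun(p), x)$lnL
    cand <- optimize_multistart(obj, rng, n_starts = 5)
    # boundary candidate that collapses to BM
    bm_par <- switch(model, OU = 0, EB = 0, lambda = 1)
    bm_lnL <- profile_gaussian(if (model == "lambda") Vfun(1) else C, x)$lnL
    if (bm_lnL > cand$objective) cand <- list(maximum = bm_par,
                                              objective = bm_lnL)
    par <- cand$maximum
    pr <- profile_gaussian(Vfun(par), x)
  }
  res <- list(model = model, sigma2 = pr$sigma2, z0 = pr$z0,
              lnL = pr$lnL, k = k, n = n,
              AICc = aicc(pr$lnL, k, n),
              binary_response = all(x %in% c(0, 1)),
              ultrametric = ultrametric_report(tree)$ultrametric)
  if (model == "OU") res$alpha <- par
  if (model == "EB") res$r <- par
  if (model == "lambda") res$lambda <- par
  class(res) <- "continuous_fit"
  res
}

# OU covariance from a precomputed BM covariance matrix
ou_cov <- function(C, alpha) {
  if (alpha < 1e-12) return(C)
  depth <- diag(C)
  D <- outer(depth, depth, "+") - 2 * C
  V <- exp(-alpha * D) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
  dimnames(V) <- dimnames(C)
  V
}

# deterministic multi-start bounded 1-D maximization
optimize_multistart <- function(f, range, n_starts = 5, tol = 1e-6) {
  cuts <- seq(range[1], range[2], length.out = n_starts + 1)
  best <- NULL
  for (i in seq_len(n_starts)) {
    o <- optimize(f, c(cuts[i], cuts[i + 1]), maximum = TRUE, tol = tol)
    if (is.null(best) || o$objective > best$objective) best <- o
  }
  best
}

align_tip_values <- function(tree, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss)) stop("tip values missing for: ",
                           paste(miss, collapse = ", "))
    x <- x[tree$tip.label]
  } else if (length(x) != length(tree$tip.label)) {
    stop("x length does not match tip count")
  } else {
    names(x) <- tree$tip.label
  }
  as.numeric(x) |> setNames(names(x))
}

#' Phylogenetic signal as Pagel's lambda
#'
#' ML lambda on `[0, lambda_max]`, with the likelihood profile at the
#' estimate and at the boundary values 0 (star structure) and 1 (Brownian
#' motion).
#'
#' @inheritParams fit_model
#' @return List: `lambda`, `lnL`, `lnL0` (lambda = 0), `lnL1` (lambda = 1),
#'   and the underlying `fit`.
#' @export
phylo_signal_lambda <- function(tree, x) {
  fit <- fit_model(tree, x, "lambda")
  x <- align_tip_values(tree, x)
  C <- vcv_matrix(tree)
  V0 <- C * 0; diag(V0) <- diag(C)
  list(lambda = fit$lambda, lnL = fit$lnL,
       lnL0 = profile_gaussian(V0, x)$lnL,
       lnL1 = profile_gaussian(C, x)$lnL,
       fit = fit)
}

#' AICc-weighted rate summary across feather regions
#'
#' For each region, AICc weights are computed across the candidate models
#' (typically BM / OU / EB fits of the same data); each model's rate
#' parameter sigma^2 is multiplied by its within-region weight, and the
#' weighted rates are summed across regions per model.
#'
#' @param fits Named list (per region) of named lists (per model) of
#'   `continuous_fit` objects.
#' @return Named numeric vector of summed weighted rates, one per model.
#' @export
weighted_rate_summary <- function(fits) {
  models <- names(fits[[1]])
  out <- setNames(numeric(length(models)), models)
  for (region in names(fits)) {
    f <- fits[[region]]
    if (!setequal(names(f), models))
      stop("region `", region, "` is missing model fits: ",
           paste(setdiff(models, names(f)), collapse = ", "))
    ic <- vapply(f[models], function(z) z$AICc, numeric(1))
    w <- aicc_weights(ic)
    rates <- vapply(f[models], function(z) z$sigma2, numeric(1))
    out <- out + w * rates
  }
  out
}

#' Ancestral states of a continuous character under Brownian motion
#'
#' GLS/ML ancestral estimates: the conditional mean (and variance) of each
#' internal node in the joint Gaussian implied by the fitted BM model.  The
#' root estimate equals the fitted root state z0.
#'
#' @inheritParams fit_model
#' @return Data frame with one row per internal node: `node` (ape number),
#'   `estimate`, `variance`.
#' @export
asr_continuous <- function(tree, x) {
  fit <- fit_model(tree, x, "BM")
  x <- align_tip_values(tree, x)
  n <- length(tree$tip.label)
  nodes <- (n + 1L):(n + tree$Nnode)
  S <- full_node_vcv(tree)
  Stt <- S[seq_len(n), seq_len(n)]
  Sat <- S[nodes, seq_len(n), drop = FALSE]
  Saa <- S[nodes, nodes, drop = FALSE]
  L <- chol(Stt)
  iStt_r <- backsolve(L, backsolve(L, x - fit$z0, transpose = TRUE))
  est <- fit$z0 + as.numeric(Sat %*% iStt_r)
  W <- t(backsolve(L, backsolve(L, t(Sat), transpose = TRUE)))
  vars <- fit$sigma2 * (diag(Saa) - rowSums(W * Sat))
  data.frame(node = nodes, estimate = est, variance = pmax(vars, 0))
}

# shared-path-length covariance over ALL nodes (tips + internal), in units
# of branch length (sigma^2 factored out)
full_node_vcv <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  dep <- node_depths(tree)
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  anc_list <- vector("list", nn)
  pre <- reorder_edges_preorder(tree)
  anc_list[[root]] <- root
  for (i in pre) {
    ch <- tree$edge[i, 2]
    anc_list[[ch]] <- c(anc_list[[tree$edge[i, 1]]], ch)
  }
  S <- matrix(0, nn, nn)
  for (u in seq_len(nn)) for (v in u:nn) {
    common <- intersect(anc_list[[u]], anc_list[[v]])
    S[u, v] <- S[v, u] <- max(dep[common])
  }
  S
}
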