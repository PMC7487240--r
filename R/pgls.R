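# Phylogenetic generalized least squares.  The residual covariance is a
# tree-derived correlation structure: pure Brownian motion (lambda = 1, the
# default), a fixed Pagel's lambda, or lambda estimated by maximum
# likelihood jointly with the coefficients.

#' Fit a phylogenetic generalized least squares model
#'
#' Estimates `beta = (X' V^-1 X)^-1 X' V^-1 y` with `V` the tree covariance
#' under the chosen correlation structure.  R-squared, the overall F test
#' and coefficient t tests are computed in the GLS-whitened space against
#' the intercept-only model under the same `V`.
#'
#' @param tree A `phylo` object.
#' @param formula Model formula, e.g. `y ~ x1 + x2`.
#' @param data Data frame with species as rownames (matched to tip labels).
#' @param correlation `"BM"` (lambda = 1), `"lambda-ML"` or
#'   `"lambda-fixed"`.
#' @param lambda Fixed lambda value when `correlation = "lambda-fixed"`.
#' @return A `pgls_result` list with coefficients, standard errors, t and p
#'   values, overall F with degrees of freedom, model p-value, R2, adjusted
#'   R2, lnL, k, AICc, n, and the correlation structure used.
#' @export
pgls_fit <- function(tree, formula, data,
                     correlation = c("BM", "lambda-ML", "lambda-fixed"),
                     lambda = 1) {
  correlation <- match.arg(correlation)
  validate_phylo(tree)
  if (is.null(rownames(data))) stop("data needs species rownames")
  miss <- setdiff(tree$tip.label, rownames(data))
  if (length(miss))
    stop("species in tree but not data: ", paste(miss, collapse = ", "))
  data <- data[tree$tip.label, , drop = FALSE]
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X) - 1L # non-intercept predictors
  if (n <= p + 2) stop("too few species for this model")
  C <- vcv_matrix(tree)

  vmat <- function(l) {
    V <- C * l; diag(V) <- diag(C); V
  }
  fit_at <- function(V) {
    L <- chol(V)
    Xw <- backsolve(L, X, transpose = TRUE)
    yw <- backsolve(L, y, transpose = TRUE)
    qr_x <- qr(Xw)
    if (qr_x$rank < ncol(Xw)) {
      drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(Xw)]]
      stop("rank-deficient design; collinear column(s): ",
           paste(drop_cols, collapse = ", "))
    }
    beta <- qr.coef(qr_x, yw)
    res <- yw - Xw %*% beta
    rss <- sum(res^2)
    ow <- backsolve(L, rep(1, n), transpose = TRUE)
    b0 <- sum(ow * yw) / sum(ow^2)
    rss0 <- sum((yw - ow * b0)^2)
    sigma2_ml <- rss / n
    lnL <- -0.5 * (n * log(2 * pi * sigma2_ml) + 2 * sum(log(diag(L))) + n)
    list(beta = beta, rss = rss, rss0 = rss0, lnL = lnL, qr = qr_x,
         L = L, Xw = Xw)
  }

  lam_used <- switch(correlation, BM = 1, `lambda-fixed` = lambda,
                     `lambda-ML` = NA_real_)
  if (correlation == "lambda-ML") {
    lmax <- min(lambda_max(C), 1.5)
    o <- optimize_multistart(function(l) fit_at(vmat(l))$lnL, c(0, lmax),
                             n_starts = 4)
    lam_used <- o$maximum
    # boundary candidates keep the profile honest
    for (lb in c(0, 1)) if (fit_at(vmat(lb))$lnL > fit_at(vmat(lam_used))$lnL)
      lam_used <- lb
  } else if (lam_used < 0 || lam_used > lambda_max(C))
    stop("lambda out of admissible range")
  f <- fit_at(vmat(lam_used))

  dfe <- n - p - 1L
  sigma2_hat <- f$rss / dfe
  XtX_inv <- solve(crossprod(f$Xw))
  se <- sqrt(diag(XtX_inv) * sigma2_hat)
  tval <- f$beta / se
  pval <- 2 * pt(abs(tval), dfe, lower.tail = FALSE)
  r2 <- 1 - f$rss / f$rss0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / dfe
  Fstat <- if (p > 0) ((f$rss0 - f$rss) / p) / (f$rss / dfe) else NA_real_
  model_p <- if (p > 0) pf(Fstat, p, dfe, lower.tail = FALSE) else NA_real_
  k <- p + 2L + (correlation == "lambda-ML")
  out <- list(response = deparse(formula[[2]]),
              predictors = setdiff(colnames(X), "(Intercept)"),
              coefficients = setNames(as.numeric(f$beta), colnames(X)),
              se = setNames(as.numeric(se), colnames(X)),
              t = setNames(as.numeric(tval), colnames(X)),
              coef_p = setNames(as.numeric(pval), colnames(X)),
              F = Fstat, df = c(p, dfe), model_p = model_p,
              r2 = r2, adj_r2 = adj_r2, lnL = f$lnL, k = k, n = n,
              AICc = aicc(f$lnL, k, n),
              correlation = correlation, lambda = lam_used)
  class(out) <- "pgls_result"
  out
}

#' @export
print.pgls_result <- function(x, ...) {
  cat("PGLS:", x$response, "~",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ")
      else "1", "\n")
  cat(sprintf("  correlation: %s (lambda = %.3f), n = %d\n",
              x$correlation, x$lambda, x$n))
  tab <- cbind(Estimate = x$coefficients, SE = x$se, t = x$t, p = x$coef_p)
  print(round(tab, 4))
  cat(sprintf("  F_%d,%d = %.3f, p = %.4g, adj R2 = %.3f, AICc = %.2f\n",
              x$df[1], x$df[2], x$F, x$model_p, x$adj_r2, x$AICc))
  invisible(x)
}

#' Rank a set of PGLS models by AICc
#'
#' Fits every candidate predictor subset for a shared response and species
#' set, then tabulates adjusted R2, model p-value, AICc, delta AICc and
#' Akaike weight, sorted ascending by AICc (ties keep input order).
#'
#' @param tree A `phylo` object.
#' @param response Response variable name (column of `data`).
#' @param model_specs List of character vectors of predictor names; an
#'   empty vector means the intercept-only model.
#' @param data Data frame with species rownames.
#' @param correlation,lambda Passed to [pgls_fit()].
#' @return Data frame, one row per model, sorted by AICc, with an
#'   `aicc_weight` column; fitted objects attached as attribute `"fits"`.
#' @export
rank_model_set <- function(tree, response, model_specs, data,
                           correlation = "BM", lambda = 1) {
  specs <- lapply(model_specs, as.character)
  fits <- lapply(specs, function(ps) {
    fm <- stats::reformulate(if (length(ps)) ps else "1",
                             response = response)
    pgls_fit(tree, fm, data, correlation = correlation, lambda = lambda)
  })
  tab <- data.frame(
    model = vapply(specs, function(ps)
      if (length(ps)) paste(ps, collapse = " + ") else "1", character(1)),
    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1)),
    p = vapply(fits, function(f) f$model_p, numeric(1)),
    lnL = vapply(fits, function(f) f$lnL, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)))
  ord <- order(tab$AICc)
  tab <- tab[ord, ]
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  tab$aicc_weight <- aicc_weights(tab$AICc)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
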