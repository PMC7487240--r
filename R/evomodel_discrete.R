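# Mk models of discrete character evolution: Felsenstein-pruning
# likelihoods, ER/ARD maximum-likelihood fits, likelihood-ratio tests,
# marginal ancestral state reconstruction, and Pagel's correlated-evolution
# test for pairs of binary characters.  The root is weighted by a flat
# prior over states by default.

# transition matrices P(t) = exp(Q t) for a set of branch lengths.
# Eigendecomposition when Q is diagonalizable (one decomposition serves all
# branches); dense scaling-and-squaring fallback for defective Q.
transition_matrices <- function(Q, times) {
  s <- nrow(Q)
  P <- array(0, dim = c(s, s, length(times)))
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  Vi <- if (!is.null(eg)) tryCatch(solve(eg$vectors), error = function(e) NULL)
  if (!is.null(Vi)) {
    # P(t) = sum_k exp(v_k t) * (V[,k] outer Vi[k,]): one matrix product
    # for all branch lengths at once
    B <- matrix(0i, s, s * s)
    for (k in seq_len(s)) B[k, ] <- as.vector(outer(eg$vectors[, k],
                                                    Vi[k, ]))
    E <- exp(outer(times, eg$values))
    Pf <- Re(E %*% B) # n_times x s^2, column-major (a, b) layout
    rs <- Pf %*% kronecker(rep(1, s), diag(s)) # row sums of each P(t)
    if (all(is.finite(Pf)) && max(abs(rs - 1)) < 1e-8 &&
        min(Pf) > -1e-10) {
      Pf[Pf < 0] <- 0
      P[] <- t(Pf)
      return(P)
    }
  }
  for (i in seq_along(times))
    P[, , i] <- as.matrix(Matrix::expm(Q * times[i]))
  P
}

validate_Q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (max(abs(rowSums(Q))) > 1e-10 * max(1, max(abs(Q))))
    stop("Q rows must sum to zero")
  invisible(Q)
}

# tip partial-likelihood matrix (tips x states) from a state vector
tip_partials <- function(tree, states, state_set) {
  states <- align_tip_states(tree, states)
  n <- length(states)
  Lp <- matrix(0, n, length(state_set))
  idx <- match(states, state_set)
  if (any(is.na(idx)))
    stop("state(s) not in model state set: ",
         paste(unique(states[is.na(idx)]), collapse = ", "))
  Lp[cbind(seq_len(n), idx)] <- 1
  Lp
}

align_tip_states <- function(tree, states) {
  if (!is.null(names(states))) {
    miss <- setdiff(tree$tip.label, names(states))
    if (length(miss)) stop("tip states missing for: ",
                           paste(miss, collapse = ", "))
    states <- states[tree$tip.label]
  } else if (length(states) != length(tree$tip.label)) {
    stop("states length does not match tip count")
  }
  states
}

# traversal cache: computed once per tree, reused across likelihood
# evaluations during optimization
mk_cache <- function(tree) {
  list(n = length(tree$tip.label),
       nn = length(tree$tip.label) + tree$Nnode,
       post = reorder_edges_postorder(tree),
       pre = reorder_edges_preorder(tree),
       children = split(seq_len(nrow(tree$edge)), tree$edge[, 1]))
}

# core pruning pass: returns per-node partial likelihoods with per-node
# scaling factors (log) to avoid underflow
prune_partials <- function(tree, Lp, Q, cache = NULL) {
  if (is.null(cache)) cache <- mk_cache(tree)
  n <- cache$n
  nn <- cache$nn
  s <- nrow(Q)
  P <- transition_matrices(Q, tree$edge.length)
  dim(P) <- c(s * s, length(tree$edge.length)) # column i = vec(P(t_i))
  sw <- prune_sweep(tree$edge[, 1], tree$edge[, 2], cache$post, P, Lp,
                    as.integer(nn), as.integer(s))
  dim(P) <- c(s, s, length(tree$edge.length))
  list(part = sw$part, logscale = sw$logscale, P = P)
}

#' Mk-model log-likelihood by Felsenstein pruning
#'
#' @param tree A `phylo` object.
#' @param states Per-tip states (named by tip label), members of
#'   `state_set`.
#' @param Q Instantaneous rate matrix (rows sum to zero, off-diagonals
#'   non-negative), with `dimnames` giving the state set.
#' @param root_prior `"flat"` (default), `"stationary"`, or a probability
#'   vector over states.
#' @return The log-likelihood.
#' @export
mk_loglik <- function(tree, states, Q, root_prior = "flat") {
  validate_phylo(tree)
  validate_Q(Q)
  state_set <- rownames(Q) %||% as.character(seq_len(nrow(Q)) - 1L)
  Lp <- tip_partials(tree, as.character(states), state_set)
  pr <- prune_partials(tree, Lp, Q)
  root <- length(tree$tip.label) + 1L
  pi0 <- root_prior_vec(root_prior, Q)
  lik <- sum(pi0 * pr$part[root, ])
  log(lik) + pr$logscale[root]
}

root_prior_vec <- function(root_prior, Q) {
  s <- nrow(Q)
  if (is.numeric(root_prior)) {
    if (length(root_prior) != s || any(root_prior < 0))
      stop("bad root prior")
    return(root_prior / sum(root_prior))
  }
  if (identical(root_prior, "flat")) return(rep(1 / s, s))
  if (identical(root_prior, "stationary")) {
    # left null vector of Q
    ev <- eigen(t(Q))
    i <- which.min(abs(ev$values))
    v <- Re(ev$vectors[, i]); v <- abs(v)
    return(v / sum(v))
  }
  stop("unknown root prior")
}

#' Fit an Mk model (equal rates or all rates different)
#'
#' ML rates by bounded multi-start optimization on the log-rate scale.  The
#' ER solution seeds the ARD search, so `lnL(ARD) >= lnL(ER)` up to
#' optimizer tolerance.
#'
#' @param tree A `phylo` object.
#' @param states Per-tip states (coerced to character); at least two
#'   distinct states must be observed.
#' @param model `"ER"` or `"ARD"`.
#' @param root_prior Passed to [mk_loglik()].
#' @return An `mk_fit` list: `Q`, `rates`, `model`, `lnL`, `k`, `AIC`,
#'   `AICc`, `state_set`, `root_prior`.
#' @export
fit_mk <- function(tree, states, model = c("ER", "ARD"),
                   root_prior = "flat") {
  model <- match.arg(model)
  validate_phylo(tree)
  states <- align_tip_states(tree, as.character(states))
  state_set <- sort(unique(states))
  s <- length(state_set)
  if (s < 2) stop("invariant character: need at least 2 observed states")
  n <- length(tree$tip.label)
  depth <- max(node_depths(tree))
  build_Q <- function(rates) {
    Q <- matrix(0, s, s, dimnames = list(state_set, state_set))
    Q[row(Q) != col(Q)] <- if (model == "ER") rates[1] else rates
    diag(Q) <- -rowSums(Q)
    Q
  }
  k <- if (model == "ER") 1L else s * (s - 1L)
  Lp <- tip_partials(tree, states, state_set)
  cache <- mk_cache(tree)
  negll <- function(logr) {
    Q <- build_Q(exp(logr))
    pr <- prune_partials(tree, Lp, Q, cache)
    root <- n + 1L
    -(log(sum(root_prior_vec(root_prior, Q) * pr$part[root, ])) +
        pr$logscale[root])
  }
  lo <- log(1e-8 / depth); hi <- log(1e3 / depth)
  if (model == "ER") {
    o <- optimize(function(lr) negll(lr), c(lo, hi), tol = 1e-8)
    rates <- exp(o$minimum); lnL <- -o$objective
  } else {
    er <- fit_mk(tree, states, "ER", root_prior)
    starts <- list(rep(log(er$rates[1]), k),
                   rep(log(er$rates[1]), k) + seq(-0.5, 0.5, length.out = k),
                   rep(log(max(er$rates[1] * 2, 1e-6 / depth)), k))
    best <- NULL
    for (st in starts) {
      o <- tryCatch(optim(st, negll, method = "L-BFGS-B",
                          lower = lo, upper = hi,
                          control = list(maxit = 500, factr = 1e8)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    rates <- exp(best$par); lnL <- -best$value
    if (lnL < er$lnL - 1e-6) { # fall back to the nested optimum
      rates <- rep(er$rates[1], k); lnL <- er$lnL
    }
  }
  Q <- build_Q(rates)
  out <- list(Q = Q, rates = unname(rates), model = model, lnL = lnL, k = k,
              n = n, AIC = -2 * lnL + 2 * k,
              AICc = aicc(lnL, k, n), state_set = state_set,
              root_prior = root_prior)
  class(out) <- "mk_fit"
  out
}

#' Likelihood-ratio test between nested models
#'
#' Statistic `2 (lnL_complex - lnL_simple)` against the chi-square upper
#' tail with `df` degrees of freedom.
#'
#' @param lnL_simple,lnL_complex Log-likelihoods of the nested and nesting
#'   model.
#' @param df Difference in free parameters.
#' @param tol Negative-statistic tolerance before an optimizer failure is
#'   flagged.
#' @return List with `statistic` and `p`.
#' @export
lrt <- function(lnL_simple, lnL_complex, df, tol = 1e-6) {
  stat <- 2 * (lnL_complex - lnL_simple)
  if (stat < -tol)
    stop("negative LRT statistic: complex model fits worse (optimizer ",
         "failure?)")
  stat <- max(stat, 0)
  list(statistic = stat, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Marginal ancestral state reconstruction
#'
#' Posterior state probabilities at every internal node given the tip data
#' and rate matrix, computed by the standard two-pass (downward partials,
#' upward flow) algorithm — equivalent to re-rooting at each node.  Each
#' node's probabilities sum to one.
#'
#' @inheritParams mk_loglik
#' @return An `asr_result` list: `prob` (internal nodes x states matrix),
#'   `map` (MAP state per node; ties broken toward the first state and
#'   flagged in `tie`), `lnL`.
#' @export
marginal_asr <- function(tree, states, Q, root_prior = "flat") {
  validate_phylo(tree)
  validate_Q(Q)
  state_set <- rownames(Q) %||% as.character(seq_len(nrow(Q)) - 1L)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  s <- nrow(Q)
  Lp <- tip_partials(tree, as.character(states), state_set)
  prn <- prune_partials(tree, Lp, Q)
  part <- prn$part; P <- prn$P
  root <- n + 1L
  pi0 <- root_prior_vec(root_prior, Q)
  lnL <- log(sum(pi0 * part[root, ])) + prn$logscale[root]
  # upward pass: up[v, ] = flow from the rest of the tree into node v
  up <- matrix(0, nn, s)
  up[root, ] <- pi0
  pre <- reorder_edges_preorder(tree)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (i in pre) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    sibs <- setdiff(children[[as.character(p)]], i)
    prod_sib <- up[p, ]
    for (j in sibs) prod_sib <- prod_sib * as.numeric(P[, , j] %*%
                                                       part[tree$edge[j, 2], ])
    up[ch, ] <- as.numeric(t(P[, , i]) %*% prod_sib)
    mx <- max(up[ch, ])
    if (mx > 0) up[ch, ] <- up[ch, ] / mx
  }
  nodes <- root:nn
  raw <- up[nodes, , drop = FALSE] * part[nodes, , drop = FALSE]
  prob <- raw / rowSums(raw)
  dimnames(prob) <- list(nodes, state_set)
  map_idx <- apply(prob, 1, which.max)
  tie <- apply(prob, 1, function(z) sum(abs(z - max(z)) < 1e-12) > 1)
  # ties break toward the first (absence) state
  map_idx[tie] <- vapply(which(tie), function(r)
    min(which(abs(prob[r, ] - max(prob[r, ])) < 1e-12)), integer(1))
  out <- list(prob = prob, map = setNames(state_set[map_idx], nodes),
              tie = tie, lnL = lnL, state_set = state_set)
  class(out) <- "asr_result"
  out
}

#' Count gains and losses along the tree
#'
#' A transition is counted on a branch whenever the MAP state of the parent
#' differs from the MAP state of the child (tips use their observed state).
#' For a binary 0/1 character, gains are 0 -> 1 and losses 1 -> 0.
#'
#' @param tree A `phylo` object.
#' @param asr An [marginal_asr()] result.
#' @param states Observed tip states.
#' @return List with `gains`, `losses`, `n_ties` (flagged MAP ties).
#' @export
count_transitions <- function(tree, asr, states) {
  states <- align_tip_states(tree, as.character(states))
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  node_state <- character(nn)
  node_state[seq_len(n)] <- states
  node_state[(n + 1L):nn] <- asr$map
  from <- node_state[tree$edge[, 1]]
  to <- node_state[tree$edge[, 2]]
  s0 <- asr$state_set[1]; s1 <- asr$state_set[2]
  list(gains = sum(from == s0 & to == s1),
       losses = sum(from == s1 & to == s0),
       n_ties = sum(asr$tie))
}

# ---- Pagel's correlated-evolution test -------------------------------------

# 4-state composite chain over two binary traits; state order 00, 01, 10, 11
# (trait x first, trait y second).  Dual transitions have rate zero.
pagel_states <- c("00", "01", "10", "11")

# independent model: 4 free rates (x: 0->1, 1->0; y: 0->1, 1->0)
pagel_Q_independent <- function(r) {
  ax <- r[1]; bx <- r[2]; ay <- r[3]; by <- r[4]
  Q <- matrix(0, 4, 4, dimnames = list(pagel_states, pagel_states))
  Q["00", "01"] <- ay; Q["00", "10"] <- ax
  Q["01", "00"] <- by; Q["01", "11"] <- ax
  Q["10", "00"] <- bx; Q["10", "11"] <- ay
  Q["11", "01"] <- bx; Q["11", "10"] <- by
  diag(Q) <- -rowSums(Q)
  Q
}

# dependent model: 8 free rates, one per single-trait transition per
# background state of the other trait
pagel_Q_dependent <- function(r) {
  Q <- matrix(0, 4, 4, dimnames = list(pagel_states, pagel_states))
  Q["00", "01"] <- r[1]; Q["00", "10"] <- r[2]
  Q["01", "00"] <- r[3]; Q["01", "11"] <- r[4]
  Q["10", "00"] <- r[5]; Q["10", "11"] <- r[6]
  Q["11", "01"] <- r[7]; Q["11", "10"] <- r[8]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Pagel's test of correlated evolution of two binary characters
#'
#' Compares an independent model — two binary chains evolving side by side,
#' giving a 4-state composite chain with 4 free rates — against a dependent
#' model in which each trait's gain and loss rates may differ according to
#' the state of the other trait (8 free rates).  Dual transitions (both
#' traits changing in one instant) have rate zero in both models.  Reports
#' AIC for both models (`AIC = -2 lnL + 2k`), AICc, and a likelihood-ratio
#' test with 4 degrees of freedom.
#'
#' @param tree A `phylo` object.
#' @param x,y Named binary (0/1) tip vectors; both must be variable.
#' @param root_prior Passed to the likelihood.
#' @return List: `fit_independent`, `fit_dependent` (rates, lnL, k, AIC,
#'   AICc), `delta_AIC` (independent minus dependent), `lrt`
#'   (statistic, p), `rates_dependent` (the 8 transition rates).
#' @export
pagel_dependence_test <- function(tree, x, y, root_prior = "flat") {
  validate_phylo(tree)
  x <- align_tip_states(tree, as.character(as.integer(x)))
  y <- align_tip_states(tree, as.character(as.integer(y)))
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("cannot test dependence with invariant character")
  combo <- paste0(x, y)
  names(combo) <- tree$tip.label
  n <- length(tree$tip.label)
  depth <- max(node_depths(tree))
  Lp <- tip_partials(tree, combo, pagel_states)
  cache <- mk_cache(tree)
  negll <- function(logr, builder) {
    Q <- builder(exp(logr))
    pr <- prune_partials(tree, Lp, Q, cache)
    root <- n + 1L
    -(log(sum(root_prior_vec(root_prior, Q) * pr$part[root, ])) +
        pr$logscale[root])
  }
  lo <- log(1e-8 / depth); hi <- log(1e3 / depth)
  fit_rates <- function(builder, k, starts) {
    best <- NULL
    for (st in starts) {
      o <- tryCatch(optim(st, negll, builder = builder, method = "L-BFGS-B",
                          lower = lo, upper = hi,
                          control = list(maxit = 500, factr = 1e8)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    list(rates = exp(best$par), lnL = -best$value, k = k)
  }
  # seed from marginal ER rates of each trait
  er_x <- fit_mk(tree, x, "ER", root_prior)$rates[1]
  er_y <- fit_mk(tree, y, "ER", root_prior)$rates[1]
  st_ind <- list(log(c(er_x, er_x, er_y, er_y)),
                 log(rep(mean(c(er_x, er_y)), 4)),
                 log(c(er_x, er_x, er_y, er_y)) + c(0.5, -0.5, 0.5, -0.5))
  ind <- fit_rates(pagel_Q_independent, 4L, st_ind)
  # dependent search seeded at the independent optimum (nesting guarantee)
  r_ind8 <- log(c(ind$rates[3], ind$rates[1], ind$rates[4], ind$rates[1],
                  ind$rates[2], ind$rates[3], ind$rates[2], ind$rates[4]))
  st_dep <- list(r_ind8, r_ind8 + 0.5)
  dep <- fit_rates(pagel_Q_dependent, 8L, st_dep)
  if (dep$lnL < ind$lnL - 1e-6) {
    dep$rates <- exp(r_ind8); dep$lnL <- ind$lnL
  }
  mk_ic <- function(f) {
    f$AIC <- -2 * f$lnL + 2 * f$k
    f$AICc <- aicc(f$lnL, f$k, n)
    f
  }
  ind <- mk_ic(ind); dep <- mk_ic(dep)
  list(fit_independent = ind, fit_dependent = dep,
       delta_AIC = ind$AIC - dep$AIC,
       lrt = lrt(ind$lnL, dep$lnL, df = 4),
       rates_dependent = setNames(dep$rates,
         c("q00_01", "q00_10", "q01_00", "q01_11",
           "q10_00", "q10_11", "q11_01", "q11_10")))
}
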