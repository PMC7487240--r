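# d-separation phylogenetic path analysis: each candidate causal DAG
# implies a basis set of conditional independencies; each claim is tested
# with a phylogenetic regression, the p-values are combined into Fisher's C
# (chi-square with 2k df), and models are ranked by the small-sample
# information criterion CICc = C + 2 q n / (n - 1 - q).

#' Construct a causal DAG
#'
#' @param edges Data frame (or 2-column matrix) with columns `from`, `to`,
#'   one directed edge per row; or an empty data frame for an edgeless
#'   graph over `vertices`.
#' @param vertices Optional vertex names (superset of those in `edges`).
#' @param id Optional model identifier.
#' @return A `causal_dag` list with `vertices`, `edges`, `order`
#'   (a topological order).  Cyclic input is an error naming the cycle.
#' @export
causal_dag <- function(edges, vertices = NULL, id = NULL) {
  if (is.matrix(edges)) edges <- data.frame(from = edges[, 1],
                                            to = edges[, 2])
  if (nrow(edges) && !all(c("from", "to") %in% names(edges)))
    stop("edges need `from` and `to` columns")
  verts <- unique(c(vertices, edges$from, edges$to))
  if (!length(verts)) stop("empty DAG")
  if (anyDuplicated(paste(edges$from, edges$to)))
    stop("duplicate edges")
  ord <- topological_order(verts, edges)
  structure(list(vertices = verts, edges = edges, order = ord, id = id),
            class = "causal_dag")
}

topological_order <- function(verts, edges) {
  indeg <- setNames(integer(length(verts)), verts)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  active <- edges
  queue <- verts[indeg == 0]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    kids <- active$to[active$from == v]
    active <- active[active$from != v, , drop = FALSE]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0) queue <- c(queue, k)
    }
  }
  if (length(out) != length(verts))
    stop("graph is cyclic; cycle involves: ",
         paste(setdiff(verts, out), collapse = ", "))
  out
}

dag_parents <- function(dag, v) dag$edges$from[dag$edges$to == v]

#' d-separation basis set of a DAG
#'
#' One conditional-independence claim per unordered non-adjacent vertex
#' pair: the causally later vertex (in topological order) is regressed on
#' the earlier one, conditioning on the union of both vertices' parents
#' (excluding the pair itself).  Claims are returned in lexicographic order
#' of the pair.
#'
#' @param dag A [causal_dag()].
#' @return List of claims, each a list `(x, y, z)`: test `y ~ x | z` with
#'   `y` the later vertex.
#' @export
basis_set <- function(dag) {
  verts <- dag$vertices
  adj <- paste(dag$edges$from, dag$edges$to)
  adj <- c(adj, paste(dag$edges$to, dag$edges$from))
  pos <- match(verts, dag$order)
  pairs <- t(combn(sort(verts), 2))
  claims <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (paste(a, b) %in% adj) next
    # later vertex in topological order is the regression response
    if (pos[match(a, verts)] <= pos[match(b, verts)]) {
      x <- a; y <- b
    } else {
      x <- b; y <- a
    }
    z <- setdiff(union(dag_parents(dag, x), dag_parents(dag, y)), c(x, y))
    claims[[length(claims) + 1L]] <- list(x = x, y = y, z = sort(z))
  }
  claims
}

#' Test a basis set with phylogenetic regressions
#'
#' Each claim `y _||_ x | z` is tested by the two-sided p-value of the
#' coefficient of `x` in `pgls_fit(y ~ x + z)` under the chosen correlation
#' structure.
#'
#' @param tree A `phylo` object.
#' @param data Data frame with species rownames holding every DAG variable.
#' @param claims Output of [basis_set()].
#' @param correlation,lambda Passed to [pgls_fit()].
#' @return The claims, each with a `p` element added.
#' @export
test_claims <- function(tree, data, claims, correlation = "BM", lambda = 1) {
  lapply(claims, function(cl) {
    rhs <- c(cl$x, cl$z)
    fm <- stats::reformulate(rhs, response = cl$y)
    fit <- pgls_fit(tree, fm, data, correlation = correlation,
                    lambda = lambda)
    cl$p <- unname(fit$coef_p[cl$x])
    cl
  })
}

#' Fisher's C statistic
#'
#' `C = -2 sum(log p_i)` over the k independence tests, compared with the
#' chi-square upper tail on `2k` degrees of freedom.  Zero p-values are
#' clamped to `1e-300` with a warning.
#'
#' @param pvalues Claim p-values in `(0, 1]`.
#' @return List: `C`, `df` (= 2k), `p`.
#' @export
fisher_c <- function(pvalues) {
  if (!length(pvalues)) stop("need at least one p-value")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must be in [0, 1]")
  if (any(pvalues == 0)) {
    warning("zero p-value clamped to 1e-300")
    pvalues[pvalues == 0] <- 1e-300
  }
  C <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

#' Small-sample information criterion for path models
#'
#' `CICc = C + 2 q n / (n - 1 - q)` with `q` the parameter count of the
#' path model and `n` the number of species.
#'
#' @param C Fisher's C.
#' @param q Parameter count (here: edges + vertices).
#' @param n Sample size; must exceed `q + 1`.
#' @return The CICc value.
#' @export
cicc <- function(C, q, n) {
  if (n <= q + 1) stop("CICc undefined: n must exceed q + 1")
  C + 2 * q * n / (n - 1 - q)
}

#' Evaluate and rank candidate path models
#'
#' For each DAG: derive the basis set, test every claim by PGLS, combine
#' into Fisher's C with its chi-square p-value, and compute CICc with
#' `q = #edges + #vertices` (each variable contributes a free variance).
#' Models with `p > alpha` (not rejected) are ranked ascending by CICc;
#' rejected models are flagged and left unranked.
#'
#' @param tree A `phylo` object.
#' @param data Data frame with species rownames.
#' @param dags List of [causal_dag()] objects (ids used as row labels).
#' @param alpha Rejection level for the C-statistic p-value.
#' @param correlation,lambda Passed to [pgls_fit()].
#' @return Data frame: model, n_claims, C, p, q, CICc, delta_CICc,
#'   rejected, rank (NA for rejected models), sorted by CICc.
#' @export
evaluate_path_models <- function(tree, data, dags, alpha = 0.05,
                                 correlation = "BM", lambda = 1) {
  if (!length(dags)) stop("need at least one DAG")
  n <- length(tree$tip.label)
  rows <- lapply(seq_along(dags), function(i) {
    dag <- dags[[i]]
    if (!all(dag$vertices %in% names(data)))
      stop("DAG variables missing from data: ",
           paste(setdiff(dag$vertices, names(data)), collapse = ", "))
    claims <- basis_set(dag)
    q <- nrow(dag$edges) + length(dag$vertices)
    if (length(claims)) {
      tested <- test_claims(tree, data, claims, correlation, lambda)
      fc <- fisher_c(vapply(tested, `[[`, numeric(1), "p"))
    } else {
      fc <- list(C = 0, df = 0L, p = 1)
    }
    data.frame(model = dag$id %||% paste0("m", i),
               n_claims = length(claims), C = fc$C, p = fc$p, q = q,
               CICc = cicc(fc$C, q, n))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$CICc), ]
  tab$delta_CICc <- tab$CICc - min(tab$CICc)
  tab$rejected <- tab$p <= alpha
  tab$rank <- NA_integer_
  tab$rank[!tab$rejected] <- seq_len(sum(!tab$rejected))
  rownames(tab) <- NULL
  tab
}

#' Read a plain-text DAG set file
#'
#' Format: blocks separated by blank lines; each block starts with
#' `id: <name>` followed by one `parent -> child` edge per line.  Lines
#' starting with `#` are comments.  A line `vertices: a b c` may declare
#' isolated vertices.
#'
#' @param path File path.
#' @return Named list of [causal_dag()] objects.
#' @export
read_dag_set <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^#", lines)]
  blocks <- split(lines, cumsum(lines == ""))
  dags <- list()
  for (b in blocks) {
    b <- b[b != ""]
    if (!length(b)) next
    idl <- grep("^id:", b, value = TRUE)
    if (!length(idl)) stop("DAG block without `id:` line")
    id <- trimws(sub("^id:", "", idl[1]))
    vl <- grep("^vertices:", b, value = TRUE)
    verts <- if (length(vl))
      strsplit(trimws(sub("^vertices:", "", vl[1])), "[ ,]+")[[1]]
    else NULL
    el <- grep("->", b, fixed = TRUE, value = TRUE)
    edges <- if (length(el)) {
      parts <- strsplit(el, "->", fixed = TRUE)
      data.frame(from = trimws(vapply(parts, `[`, character(1), 1)),
                 to = trimws(vapply(parts, `[`, character(1), 2)))
    } else data.frame(from = character(0), to = character(0))
    dags[[id]] <- causal_dag(edges, vertices = verts, id = id)
  }
  dags
}
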