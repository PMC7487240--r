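# Trees are stored as ape "phylo" objects throughout; these helpers add the
# validation and covariance machinery the comparative analyses need.

#' Read a rooted, branch-length Newick tree
#'
#' Parses a Newick string (or a file containing one) into an `ape::phylo`
#' object and validates it for comparative use: a single root, unique tip
#' labels, non-negative branch lengths, and at least two tips.  Unlabeled
#' internal nodes are given stable synthetic ids (`nd<number>`).
#'
#' @param text A Newick string.
#' @param file Alternatively, path to a file whose first tree is read.
#' @return A validated `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    stop("supply either `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: no tree found in input")
  validate_phylo(tr)
  if (is.null(tr$node.label) || any(tr$node.label == "")) {
    lab <- paste0("nd", seq_len(tr$Nnode))
    if (!is.null(tr$node.label)) {
      keep <- tr$node.label != ""
      lab[keep] <- tr$node.label[keep]
    }
    tr$node.label <- lab
  }
  tr
}

# cheap structural scan so malformed input reports a character offset
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unbalanced ')' at character %d", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf(
      "Newick parse error: %d unclosed '(' by character %d",
      depth, length(chars)), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop(sprintf("Newick parse error: missing ';' terminator at character %d",
                 length(chars)), call. = FALSE)
  invisible(TRUE)
}

#' Serialize a tree back to Newick
#' @param tree A `phylo` object.
#' @return A Newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks single-rootedness, unique tip labels, branch lengths present and
#' non-negative, and tip count >= 2.  Called by every model-fitting entry
#' point; invalid trees raise an error.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("validation error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths not allowed")
  # each non-root node has exactly one parent
  n <- length(tree$tip.label)
  kids <- tree$edge[, 2]
  if (anyDuplicated(kids)) stop("a node has more than one parent")
  roots <- setdiff(tree$edge[, 1], kids)
  if (length(roots) != 1) stop("tree must have exactly one root")
  invisible(tree)
}

#' Node depths (distance from the root)
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over all nodes (tips first, ape numbering) of
#'   root-to-node path length.
#' @export
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  root <- n + 1L
  # preorder: parents before children
  ord <- reorder_edges_preorder(tree)
  for (i in ord) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    depth[ch] <- depth[p] + tree$edge.length[i]
  }
  depth
}

# indices into the original edge matrix, parents before children
reorder_edges_preorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  key0 <- paste(tree$edge[, 1], tree$edge[, 2])
  keyp <- paste(tr$edge[, 1], tr$edge[, 2])
  rev(match(keyp, key0))
}

# indices into the original edge matrix, children before parents
reorder_edges_postorder <- function(tree) {
  rev(reorder_edges_preorder(tree))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phylogenetic variance-covariance matrix
#'
#' The matrix C with `C[i, j]` the root-to-MRCA path length of tips i and j
#' and `C[i, i]` the depth of tip i: the covariance structure of a trait
#' evolving by Brownian motion (up to the rate).
#'
#' @param tree A `phylo` object.
#' @return An n x n symmetric matrix with tip labels as dimnames.
#' @export
vcv_matrix <- function(tree) {
  validate_phylo(tree)
  ape::vcv.phylo(tree)
}

#' Ultrametricity diagnostic
#'
#' Reports, never enforces: the spread between the deepest and shallowest
#' tip relative to tree depth, and whether it is within tolerance
#' (`1e-6 * depth` by default).
#'
#' @param tree A `phylo` object.
#' @param tol Absolute tolerance; defaults to `1e-6 * max depth`.
#' @return List with `depth_range`, `max_depth`, `ultrametric` (logical).
#' @export
ultrametric_report <- function(tree, tol = NULL) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  if (is.null(tol)) tol <- 1e-6 * max(d)
  list(depth_range = max(d) - min(d), max_depth = max(d),
       ultrametric = (max(d) - min(d)) < tol)
}

#' Largest admissible Pagel's lambda
#'
#' The largest multiplier on the off-diagonal of C that keeps the matrix
#' positive semi-definite.  For an ultrametric tree this is at least 1.
#'
#' @param C A phylogenetic covariance matrix.
#' @return A scalar upper bound for lambda.
#' @export
lambda_max <- function(C) {
  off <- C; diag(off) <- 0
  if (all(off == 0)) return(Inf)
  # pairwise correlation bound, then verify/shrink by eigenvalue bisection
  dd <- diag(C)
  bound <- Inf
  n <- nrow(C)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (C[i, j] > 0) bound <- min(bound, sqrt(dd[i] * dd[j]) / C[i, j])
  }
  psd_at <- function(l) {
    M <- off * l; diag(M) <- dd
    min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) >=
      -1e-8 * sum(dd)
  }
  if (psd_at(bound)) return(bound)
  lo <- 1; hi <- bound
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (psd_at(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Model-implied covariance transforms
#'
#' Produces the tip covariance matrix implied by a branch-length transform of
#' the tree:
#' \describe{
#'   \item{lambda}{off-diagonal entries of C multiplied by `param` (Pagel's
#'     lambda); diagonal unchanged. `param` must lie in `[0, lambda_max(C)]`.}
#'   \item{ou}{fixed-root Ornstein-Uhlenbeck with pull `alpha = param >= 0`:
#'     `V[i,j] = exp(-alpha * d[i,j]) * (1 - exp(-2 * alpha * T[i,j])) /
#'     (2 * alpha)` with `T` the shared (root-to-MRCA) time and `d` the
#'     tip-to-tip patristic distance; the stationary variance factor sigma^2
#'     is left out.  As `alpha -> 0` this tends to the Brownian C.}
#'   \item{eb}{early burst with decay `r = param <= 0`: every branch spanning
#'     ages `t1 -> t2` is replaced by `(exp(r*t2) - exp(r*t1)) / r`, then the
#'     standard covariance is taken. `r = 0` recovers Brownian motion.}
#' }
#'
#' @param tree A `phylo` object.
#' @param model One of `"lambda"`, `"ou"`, `"eb"`.
#' @param param The transform parameter (lambda, alpha, or r).
#' @return A covariance matrix over tips.
#' @export
transform_tree <- function(tree, model = c("lambda", "ou", "eb"), param) {
  model <- match.arg(model)
  C <- vcv_matrix(tree)
  switch(model,
    lambda = {
      lmax <- lambda_max(C)
      if (param < 0 || param > lmax + 1e-12)
        stop("lambda out of range [0, ", signif(lmax, 6), "]")
      V <- C * param
      diag(V) <- diag(C)
      V
    },
    ou = {
      if (param < 0) stop("OU alpha must be >= 0")
      depth <- diag(C)
      D <- outer(depth, depth, "+") - 2 * C # patristic distances
      if (param < 1e-12) return(C)
      V <- exp(-param * D) * (1 - exp(-2 * param * C)) / (2 * param)
      dimnames(V) <- dimnames(C)
      V
    },
    eb = {
      if (param > 0) stop("EB r must be <= 0")
      if (param == 0) return(C)
      tr2 <- tree
      dep <- node_depths(tree)
      t1 <- dep[tree$edge[, 1]]
      t2 <- dep[tree$edge[, 2]]
      tr2$edge.length <- (exp(param * t2) - exp(param * t1)) / param
      ape::vcv.phylo(tr2)
    })
}

#' Prune tree and data tables to a common species set
#'
#' Drops tips missing from the data and rows missing from the tree,
#' reporting both sides.
#'
#' @param tree A `phylo` object.
#' @param species Character vector of species labels present in the data.
#' @return List with `tree`, `species` (the intersection in tree order),
#'   `dropped_from_tree`, `dropped_from_data`.
#' @export
prune_to_common <- function(tree, species) {
  keep <- intersect(tree$tip.label, species)
  if (length(keep) < 2) stop("fewer than 2 species shared by tree and data")
  dropped_tree <- setdiff(tree$tip.label, keep)
  dropped_data <- setdiff(species, keep)
  tr <- if (length(dropped_tree)) ape::drop.tip(tree, dropped_tree) else tree
  list(tree = tr, species = tr$tip.label,
       dropped_from_tree = dropped_tree, dropped_from_data = dropped_data)
}

# internal: check PSD within tolerance 1e-8 * trace
is_psd <- function(V) {
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -1e-8 * sum(diag(V))
}
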