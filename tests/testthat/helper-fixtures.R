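# Shared fixtures and independent brute-force oracles used across tests.

tree3 <- function() read_newick("((A:1,B:1):1,C:2);")
tree2 <- function() read_newick("(A:1,B:1);")

# brute-force Mk likelihood on the 3-tip tree by enumerating internal
# states; independent of the pruning implementation
mk_loglik_enum3 <- function(Q, states, prior = rep(1 / nrow(Q), nrow(Q))) {
  P1 <- as.matrix(Matrix::expm(Q * 1))
  P2 <- as.matrix(Matrix::expm(Q * 2))
  idx <- match(states[c("A", "B", "C")], rownames(Q))
  tot <- 0
  for (r in seq_len(nrow(Q))) for (m in seq_len(nrow(Q))) {
    tot <- tot + prior[r] * P1[r, m] * P1[m, idx[1]] * P1[m, idx[2]] *
      P2[r, idx[3]]
  }
  log(tot)
}

# brute-force marginal state probabilities at the two internal nodes of the
# 3-tip tree (ape numbering: root = 4, AB ancestor = 5)
mk_marginals_enum3 <- function(Q, states, prior = rep(1 / nrow(Q), nrow(Q))) {
  P1 <- as.matrix(Matrix::expm(Q * 1))
  P2 <- as.matrix(Matrix::expm(Q * 2))
  idx <- match(states[c("A", "B", "C")], rownames(Q))
  s <- nrow(Q)
  joint <- matrix(0, s, s) # [root, mrca]
  for (r in seq_len(s)) for (m in seq_len(s)) {
    joint[r, m] <- prior[r] * P1[r, m] * P1[m, idx[1]] * P1[m, idx[2]] *
      P2[r, idx[3]]
  }
  list(root = rowSums(joint) / sum(joint),
       mrca = colSums(joint) / sum(joint))
}

# brute-force shared-path covariance by walking to the MRCA per tip pair
vcv_brute <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(i) {
    nodes <- i
    while (parent[i] != 0) {
      i <- parent[i]
      nodes <- c(nodes, i)
    }
    nodes
  }
  depth_of <- function(i) {
    d <- 0
    while (parent[i] != 0) {
      d <- d + elen[i]
      i <- parent[i]
    }
    d
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in i:n) {
    common <- intersect(path_to_root(i), path_to_root(j))
    C[i, j] <- C[j, i] <- max(vapply(common, depth_of, numeric(1)))
  }
  C
}

# brute-force Holm adjustment straight from the definition
holm_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}
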