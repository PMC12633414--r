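# Independent oracles used across the suite: brute-force likelihood and
# posterior enumeration, sort-based BH, exact binomial tails, and small
# fixture builders.  These stay deliberately independent of the package's
# pruning/vectorised implementations.

# All base assignments to the internal nodes of a tree, enumerated, to
# compute the joint likelihood of one column by brute force (JC, uniform
# root prior).  `leaf_codes` is a named integer vector (0 = absent).
brute_force_column <- function(tree, leaf_codes) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  parent <- rep(NA_integer_, n_tip + n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lens <- rep(NA_real_, n_tip + n_node)
  lens[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  internal <- seq.int(n_tip + 1L, n_tip + n_node)
  p_same <- function(t) 0.25 + 0.75 * exp(-4 * t / 3)
  p_diff <- function(t) 0.25 - 0.25 * exp(-4 * t / 3)
  edge_p <- function(a, b, t) ifelse(a == b, p_same(t), p_diff(t))
  grid <- as.matrix(expand.grid(rep(list(1:4), n_node)))
  codes <- leaf_codes[tree$tip.label]
  joint <- apply(grid, 1, function(states) {
    full <- c(codes, states)
    pr <- 0.25   # root prior
    for (v in seq_along(full)) {
      if (v == root) next
      if (v <= n_tip && full[v] == 0L) next   # absent leaf: no term
      pr <- pr * edge_p(full[v], full[parent[v]], lens[v])
    }
    pr
  })
  # marginal posterior at each internal node
  post <- sapply(seq_len(n_node), function(j) {
    vapply(1:4, function(b) sum(joint[grid[, j] == b]), numeric(1))
  })
  post <- sweep(post, 2, colSums(post), "/")
  colnames(post) <- if (!is.null(tree$node.label)) tree$node.label else
    paste0("node", internal)
  list(likelihood = sum(joint), posterior = post)
}

# Step-up BH, written against the textbook definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact upper binomial tail by direct summation of the pmf (log-space
# binomial coefficients for numerical stability).
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# A random rooted binary tree with named internals and modest branch
# lengths, for enumeration-scale checks.
random_small_tree <- function(n_tip, t_max = 0.4) {
  tr <- ape::rtree(n_tip, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), 0.01, t_max)
  tr$tip.label <- paste0("L", seq_len(n_tip))
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}

# Random leaf codes with some absences.
random_column <- function(n_tip, p_absent = 0.2) {
  code <- sample(0:4, n_tip, replace = TRUE,
                 prob = c(p_absent, rep((1 - p_absent) / 4, 4)))
  names(code) <- paste0("L", seq_len(n_tip))
  code
}

# A tiny three-leaf alignment fixture with known structure.
toy_alignment <- function() {
  prob_alignment(list(
    ref = strsplit("ACGTACGTAC", "")[[1]],
    s2  = strsplit("ACGTAC-TAC", "")[[1]],
    s3  = strsplit("ACATACGTAC", "")[[1]]
  ))
}
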