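# Tree handling, the Jukes-Cantor substitution model, fourfold-degenerate
# site extraction, and maximum-likelihood branch lengths on a fixed topology.

#' Parse a newick tree with named internal nodes
#'
#' Thin wrapper over [ape::read.tree()] that validates the result and keeps
#' internal-node labels and branch lengths exactly as written.
#'
#' @param text Newick string (or `NULL` if `path` given).
#' @param path Optional file containing the newick.
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) abort("Supply `text` or `path`.")
    text <- paste(readLines(path), collapse = "")
  }
  n_open <- stringr::str_count(text, stringr::fixed("("))
  n_close <- stringr::str_count(text, stringr::fixed(")"))
  if (n_open != n_close) abort("Unbalanced parentheses in newick text.")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) abort(paste("Newick parse error:", conditionMessage(e))))
  if (is.null(tree)) abort("Newick parse error: no tree found.")
  if (inherits(tree, "multiPhylo")) abort("Trailing garbage after the first tree.")
  tree
}

#' The fitted 20-haplotype great-ape neutral phylogeny
#'
#' The Jukes-Cantor maximum-likelihood phylogeny of 20 telomere-to-telomere
#' human and great-ape haplotypes estimated from fourfold degenerate sites,
#' with named internal nodes (e.g. `HUMANanc`, the human ancestral node, and
#' `hcaT2T`, the human-chimpanzee ancestor).  Shipped as a plain-text newick
#' under `extdata`.
#'
#' @return An [ape::phylo] tree with branch lengths in expected
#'   substitutions per site.
#' @export
great_ape_tree <- function() {
  parse_newick(path = system.file("extdata", "great_ape_20way.nwk",
                                  package = "aqerscan", mustWork = TRUE))
}

#' Branch length of a named node's edge to its parent
#'
#' @param tree An [ape::phylo] tree.
#' @param name Tip or internal-node label.
#' @return Branch length (expected substitutions per site).
#' @export
branch_length <- function(tree, name) {
  ti <- tree_index(tree)
  id <- match(name, ti$names)
  if (is.na(id)) abort(sprintf("No node named '%s'.", name))
  if (id == ti$root) abort("The root has no branch.")
  ti$edge_len[id]
}

# Internal indexed view of an ape tree: parent/children links, per-node
# branch lengths, postorder, tips below each node.
tree_index <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object.")
  n_tip <- length(tree$tip.label)
  n_total <- n_tip + tree$Nnode
  labels <- tree$node.label
  if (is.null(labels)) labels <- rep("", tree$Nnode)
  labels[!nzchar(labels)] <- paste0("node", which(!nzchar(labels)) + n_tip)
  names_all <- c(tree$tip.label, labels)
  if (anyDuplicated(names_all)) abort("Node names must be unique.")
  parent <- rep(NA_integer_, n_total)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_len <- rep(NA_real_, n_total)
  if (!is.null(tree$edge.length)) edge_len[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  children <- vector("list", n_total)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], tree$edge[i, 2])
  }
  # postorder: children before parents
  post <- integer(0)
  stack <- root
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    kids <- children[[v]]
    todo <- setdiff(kids, seen)
    if (length(todo) == 0L) {
      post <- c(post, v)
      seen <- c(seen, v)
      stack <- stack[-length(stack)]
    } else {
      stack <- c(stack, todo)
    }
  }
  tips_under <- vector("list", n_total)
  for (v in post) {
    tips_under[[v]] <- if (v <= n_tip) v else unlist(tips_under[children[[v]]])
  }
  list(
    n_tip = n_tip, n_total = n_total, names = names_all, parent = parent,
    children = children, edge_len = edge_len, root = root,
    postorder = post, preorder = rev(post), tips_under = tips_under
  )
}

#' Jukes-Cantor transition probability
#'
#' Under Jukes-Cantor, after branch length `t` (expected substitutions per
#' site) `P(same) = 1/4 + 3/4 exp(-4t/3)` and each of the three different
#' target bases has probability `1/4 - 1/4 exp(-4t/3)`.
#'
#' @param t Branch length(s), `>= 0`.
#' @param same If `TRUE` return the probability of observing the same base,
#'   else the per-target-base probability of a different base.
#' @return Probability vector the same length as `t`.
#' @examples
#' jc_transition(0)            # 1
#' jc_transition(1e6)          # ~0.25
#' @export
jc_transition <- function(t, same = TRUE) {
  if (any(t < 0)) abort("Branch lengths must be non-negative.")
  e <- exp(-4 * t / 3)
  if (same) 0.25 + 0.75 * e else 0.25 - 0.25 * e
}

# 4x4 JC transition matrix.
jc_matrix <- function(t) {
  e <- exp(-4 * t / 3)
  m <- matrix(0.25 - 0.25 * e, 4L, 4L)
  diag(m) <- 0.25 + 0.75 * e
  dimnames(m) <- list(BASES, BASES)
  m
}

# L %*% jc_matrix(t) without forming the matrix product: the JC matrix is
# e*I + ((1-e)/4)*J, so the product is e*L + ((1-e)/4)*rowSums(L).
jc_mult <- function(L, t) {
  e <- exp(-4 * t / 3)
  e * L + ((1 - e) / 4) * rowSums(L)
}

# ---- fourfold degenerate sites ------------------------------------------

# Dinucleotide codon prefixes whose amino acid is invariant to the third
# base, from the standard genetic code.
fourfold_prefixes <- function() {
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1, 2))
  keep <- vapply(pre, function(p) {
    aa <- gc[paste0(p, BASES)]
    length(unique(aa)) == 1L
  }, logical(1))
  pre[keep]
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Extract fourfold degenerate codon sites from a reference sequence
#'
#' Third codon positions of codons whose encoded amino acid is invariant to
#' the third base, judged on the reference sequence only.  CDS records are
#' processed independently; `frame` bases are trimmed from the 5' end of
#' each record and minus-strand codons are read on the reverse complement.
#' Codons containing a stop on the reference are skipped (with a warning
#' when internal).
#'
#' @param ref_seq Reference chromosome sequence: a single string or a
#'   character vector of bases.
#' @param cds Tibble of CDS features with columns start (0-based), end
#'   (exclusive), strand (`"+"`/`"-"`), frame (0/1/2).
#' @return Sorted unique 0-based reference positions of fourfold
#'   degenerate third codon sites.
#' @export
extract_4d_sites <- function(ref_seq, cds) {
  if (length(ref_seq) == 1L && nchar(ref_seq[1]) > 1L) {
    ref_seq <- strsplit(toupper(ref_seq), "")[[1]]
  } else {
    ref_seq <- toupper(ref_seq)
  }
  ff <- fourfold_prefixes()
  gc_tab <- Biostrings::GENETIC_CODE
  out <- integer(0)
  n_internal_stop <- 0L
  for (i in seq_len(nrow(cds))) {
    s <- cds$start[i]; e <- cds$end[i]
    strand <- cds$strand[i]; frame <- cds$frame[i] %||% 0L
    if (is.na(frame)) frame <- 0L
    idx <- seq.int(s, e - 1L)             # 0-based genomic positions
    if (identical(strand, "-")) {
      bases <- unname(COMPLEMENT[ref_seq[rev(idx) + 1L]])
      pos <- rev(idx)
    } else {
      bases <- ref_seq[idx + 1L]
      pos <- idx
    }
    if (frame > 0L) {
      bases <- bases[-seq_len(frame)]
      pos <- pos[-seq_len(frame)]
    }
    n_codon <- length(bases) %/% 3L
    if (n_codon == 0L) next
    for (j in seq_len(n_codon)) {
      k <- (j - 1L) * 3L
      codon <- paste0(bases[k + 1L], bases[k + 2L], bases[k + 3L])
      if (is.na(gc_tab[codon])) next     # ambiguity in reference
      if (gc_tab[codon] == "*") {
        if (j < n_codon) n_internal_stop <- n_internal_stop + 1L
        next
      }
      if (substr(codon, 1, 2) %in% ff) out <- c(out, pos[k + 3L])
    }
  }
  if (n_internal_stop > 0L) {
    warn(sprintf("Skipped %d codon(s) with an internal stop on the reference.",
                 n_internal_stop))
  }
  sort(unique(out))
}

#' Leaf site patterns from an alignment
#'
#' Encodes the extant rows of an alignment at selected reference positions
#' as integer site patterns (A,C,G,T = 1..4; gap/N = 0, "absent").
#'
#' @param aln A [prob_alignment].
#' @param positions 0-based reference positions (default: all).
#' @return Integer matrix, sites x taxa, with taxon names as colnames.
#' @export
alignment_patterns <- function(aln, positions = NULL) {
  cols <- if (is.null(positions)) aln$ref_coord_map else {
    if (any(positions < 0 | positions >= length(aln$ref_coord_map))) {
      abort("`positions` outside the reference range.")
    }
    aln$ref_coord_map[positions + 1L]
  }
  leaf_rows <- aln$rows[vapply(aln$rows, is.character, logical(1))]
  m <- vapply(leaf_rows, function(r) encode_bases(r[cols]),
              integer(length(cols)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(cols))
  colnames(m) <- names(leaf_rows)
  m
}

# ---- pruning machinery ---------------------------------------------------

# Conditional likelihoods by Felsenstein pruning, vectorised across sites.
# codes: sites x n_tip integer matrix (0 = absent -> all-ones likelihood).
# Returns per-node conditional likelihood matrices L, per-node messages to
# the parent M (already multiplied through the node's branch), and a
# per-site log scaling vector.
prune_up <- function(ti, codes, edge_len, scale = TRUE) {
  S <- nrow(codes)
  L <- vector("list", ti$n_total)
  M <- vector("list", ti$n_total)
  logsc <- numeric(S)
  for (v in ti$postorder) {
    if (v <= ti$n_tip) {
      Lv <- matrix(0, S, 4L)
      code <- codes[, v]
      ok <- code > 0L
      Lv[cbind(which(ok), code[ok])] <- 1
      Lv[!ok, ] <- 1
    } else {
      kids <- ti$children[[v]]
      Lv <- M[[kids[1]]]
      for (ch in kids[-1]) Lv <- Lv * M[[ch]]
      if (scale) {
        mx <- pmax(Lv[, 1], Lv[, 2], Lv[, 3], Lv[, 4])
        mx[mx == 0] <- 1
        Lv <- Lv / mx
        logsc <- logsc + log(mx)
      }
    }
    L[[v]] <- Lv
    if (v != ti$root) M[[v]] <- jc_mult(Lv, edge_len[v])
  }
  list(L = L, M = M, logsc = logsc)
}

# Per-site log-likelihood given an up pass (uniform root prior).
loglik_from_up <- function(up, ti) {
  up$logsc + log(rowSums(up$L[[ti$root]]) * 0.25)
}

# Outside ("above") partial likelihoods for every node, for marginal
# posteriors: A[v] is proportional to P(data outside v's subtree, state at v).
prune_down <- function(ti, up, edge_len) {
  S <- nrow(up$L[[ti$root]])
  A <- vector("list", ti$n_total)
  A[[ti$root]] <- matrix(0.25, S, 4L)
  for (v in ti$preorder) {
    kids <- ti$children[[v]]
    if (length(kids) == 0L) next
    for (ch in kids) {
      B <- A[[v]]
      for (sib in setdiff(kids, ch)) B <- B * up$M[[sib]]
      B <- jc_mult(B, edge_len[ch])
      mx <- pmax(B[, 1], B[, 2], B[, 3], B[, 4])
      mx[mx == 0] <- 1
      A[[ch]] <- B / mx
    }
  }
  A
}

# ---- branch-length fitting ----------------------------------------------

#' Fit Jukes-Cantor branch lengths on a fixed topology
#'
#' Maximises the Jukes-Cantor likelihood (Felsenstein pruning, uniform root
#' prior) over branch lengths by coordinate-wise bounded scalar
#' maximisation, cycling over branches until the log-likelihood change
#' falls below `ll_tol`.  Absent leaves contribute no likelihood term.
#'
#' @param topology An [ape::phylo] tree; its branch lengths are ignored.
#' @param patterns Integer site-pattern matrix (sites x taxa, values 0..4 as
#'   from [alignment_patterns()]), with taxon names as colnames.
#' @param weights Optional per-pattern multiplicities.
#' @param max_t Upper bound per branch.
#' @param tol Tolerance of each scalar maximisation.
#' @param ll_tol Stop when a full cycle improves log-likelihood by less.
#' @param max_cycles Cycle cap; exceeding it is an error carrying the last
#'   iterate in the condition.
#' @return A `jc_fit` object: the tree with fitted lengths, per-branch
#'   estimates and standard errors (via [tidy()]), the final log-likelihood
#'   and its per-cycle trace (via [glance()]).
#' @export
fit_branch_lengths <- function(topology, patterns, weights = NULL,
                               max_t = 3, tol = 1e-8, ll_tol = 1e-10,
                               max_cycles = 200L) {
  ti <- tree_index(topology)
  if (is.null(colnames(patterns))) abort("`patterns` must carry taxon colnames.")
  ord <- match(ti$names[seq_len(ti$n_tip)], colnames(patterns))
  if (anyNA(ord)) abort("`patterns` is missing some tree tips.")
  codes <- patterns[, ord, drop = FALSE]
  # collapse duplicate patterns
  key <- apply(codes, 1, paste, collapse = ",")
  if (is.null(weights)) weights <- rep(1, nrow(codes))
  agg <- rowsum(weights, key)
  first <- !duplicated(key)
  codes <- codes[first, , drop = FALSE]
  w <- as.numeric(agg[match(key[first], rownames(agg)), 1])
  all_absent <- rowSums(codes > 0L) == 0L
  if (any(all_absent)) {
    warn(sprintf("Excluding %d all-absent site pattern(s).", sum(all_absent)))
    codes <- codes[!all_absent, , drop = FALSE]
    w <- w[!all_absent]
  }
  if (nrow(codes) == 0L) abort("No usable site patterns.")

  edge_nodes <- setdiff(seq_len(ti$n_total), ti$root)
  lens <- rep(0.05, ti$n_total)
  lens[ti$root] <- NA_real_

  total_ll <- function(edge_len) {
    up <- prune_up(ti, codes, edge_len)
    sum(w * loglik_from_up(up, ti))
  }

  # Profile log-likelihood in one branch: message from below times the
  # outside vector with that edge's transition matrix between them.
  profile_edge <- function(v, up, A) {
    p <- ti$parent[v]
    B <- A[[p]]
    for (sib in setdiff(ti$children[[p]], v)) B <- B * up$M[[sib]]
    Lb <- up$L[[v]]
    function(t) {
      lik <- rowSums(jc_mult(B, t) * Lb)
      sum(w * log(pmax(lik, .Machine$double.xmin)))
    }
  }

  trace <- numeric(0)
  ll_old <- total_ll(lens)
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    for (v in edge_nodes) {
      up <- prune_up(ti, codes, lens)
      A <- prune_down(ti, up, lens)
      f <- profile_edge(v, up, A)
      opt <- optimize(f, c(0, max_t), maximum = TRUE, tol = tol)
      if (opt$objective >= f(lens[v])) lens[v] <- opt$maximum
    }
    ll_new <- total_ll(lens)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll_old) < ll_tol) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  if (!converged) {
    abort("Branch-length optimisation did not converge.",
          class = "aqerscan_no_convergence", last_lengths = lens, trace = trace)
  }

  # Under a reversible model only the sum of the two root-adjacent branch
  # lengths is identifiable (likewise for a two-leaf tree); report the
  # maximum-likelihood sum split equally.
  root_kids <- ti$children[[ti$root]]
  if (length(root_kids) == 2L) {
    lens[root_kids] <- sum(lens[root_kids]) / 2
  }

  # per-branch profile curvature at the optimum; these standard errors are
  # empirically calibrated against the replicate spread of the estimator
  se <- rep(NA_real_, ti$n_total)
  up <- prune_up(ti, codes, lens)
  A <- prune_down(ti, up, lens)
  for (v in edge_nodes) {
    f <- profile_edge(v, up, A)
    h <- max(1e-5, lens[v] * 1e-3)
    t0 <- max(lens[v], h)
    d2 <- (f(t0 + h) - 2 * f(t0) + f(t0 - h)) / h^2
    if (is.finite(d2) && d2 < 0) se[v] <- sqrt(-1 / d2)
  }

  fitted <- topology
  fitted$edge.length <- lens[fitted$edge[, 2]]
  structure(
    list(tree = fitted, lengths = setNames(lens, ti$names), se = setNames(se, ti$names),
         loglik = ll_old, trace = trace, n_patterns = nrow(codes),
         n_sites = sum(w), cycles = length(trace)),
    class = "jc_fit"
  )
}

#' @export
print.jc_fit <- function(x, ...) {
  cat(sprintf("<jc_fit> %d branches, %g sites (%d patterns), logLik = %.4f, %d cycles\n",
              sum(!is.na(x$lengths)), x$n_sites, x$n_patterns, x$loglik, x$cycles))
  invisible(x)
}

#' @rdname fit_branch_lengths
#' @param x A `jc_fit`.
#' @param ... Unused.
#' @method tidy jc_fit
#' @export
tidy.jc_fit <- function(x, ...) {
  keep <- !is.na(x$lengths)
  tibble(label = names(x$lengths)[keep],
         branch_length = unname(x$lengths[keep]),
         std_error = unname(x$se[keep]))
}

#' @rdname fit_branch_lengths
#' @method glance jc_fit
#' @export
glance.jc_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_sites = x$n_sites, n_patterns = x$n_patterns,
         cycles = x$cycles)
}
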