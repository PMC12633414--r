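# Per-column ancestral inference: which internal nodes carry a base, the
# posterior base-probability vector at each such node, and polarization of
# population variants against a reconstructed ancestor.

#' Infer per-column presence of internal nodes
#'
#' An internal node carries a base at a column iff at least two of its
#' incident lineage directions hold a present leaf: each child subtree is
#' one direction, and (for non-root nodes) the complement reached through
#' the parent is another.  This treats aligned bases as sharing a common
#' origin: a base must be witnessed on two independent lineages.
#'
#' @param leaf_present Logical matrix, sites x taxa (colnames = tip labels).
#' @param tree An [ape::phylo] tree covering those taxa.
#' @return Logical matrix, sites x internal nodes (colnames = node labels).
#' @export
infer_presence <- function(leaf_present, tree) {
  ti <- tree_index(tree)
  if (is.null(colnames(leaf_present))) abort("`leaf_present` needs taxon colnames.")
  ord <- match(ti$names[seq_len(ti$n_tip)], colnames(leaf_present))
  if (anyNA(ord)) abort("`leaf_present` is missing some tree tips.")
  lp <- leaf_present[, ord, drop = FALSE]
  S <- nrow(lp)
  # present-leaf counts below every node
  cnt <- matrix(0L, S, ti$n_total)
  cnt[, seq_len(ti$n_tip)] <- lp
  for (v in ti$postorder) {
    if (v > ti$n_tip) {
      for (ch in ti$children[[v]]) cnt[, v] <- cnt[, v] + cnt[, ch]
    }
  }
  total <- cnt[, ti$root]
  internal <- seq.int(ti$n_tip + 1L, ti$n_total)
  out <- matrix(FALSE, S, length(internal))
  colnames(out) <- ti$names[internal]
  for (j in seq_along(internal)) {
    v <- internal[j]
    occ <- matrix(0L, S, 1L)
    for (ch in ti$children[[v]]) occ <- occ + (cnt[, ch] > 0L)
    if (v != ti$root) occ <- occ + (total - cnt[, v] > 0L)
    out[, j] <- occ >= 2L
  }
  out
}

#' Marginal posterior base probabilities at internal nodes
#'
#' Felsenstein pruning under Jukes-Cantor with a uniform root prior,
#' conditioning only on present leaves (absent leaves contribute no
#' likelihood term).  Returns the marginal posterior of A,C,G,T at each
#' requested internal node, per column.
#'
#' @param codes Integer matrix, sites x taxa (A,C,G,T = 1..4, absent = 0),
#'   colnames = tip labels.
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param nodes Internal-node labels to report (default: all).
#' @return Named list of sites x 4 probability matrices.
#' @export
compute_posteriors <- function(codes, tree, nodes = NULL) {
  ti <- tree_index(tree)
  ord <- match(ti$names[seq_len(ti$n_tip)], colnames(codes))
  if (anyNA(ord)) abort("`codes` is missing some tree tips.")
  codes <- codes[, ord, drop = FALSE]
  if (any(is.na(ti$edge_len[-ti$root]))) abort("Tree must carry branch lengths.")
  internal <- ti$names[seq.int(ti$n_tip + 1L, ti$n_total)]
  nodes <- nodes %||% internal
  bad <- setdiff(nodes, internal)
  if (length(bad)) abort(sprintf("Not internal nodes: %s", paste(bad, collapse = ", ")))
  up <- prune_up(ti, codes, ti$edge_len)
  A <- prune_down(ti, up, ti$edge_len)
  out <- lapply(nodes, function(nm) {
    v <- match(nm, ti$names)
    post <- A[[v]] * up$L[[v]]
    sums <- rowSums(post)
    sums[sums == 0] <- 1
    post <- post / sums
    colnames(post) <- BASES
    post
  })
  names(out) <- nodes
  out
}

#' Reconstruct ancestral rows of an alignment
#'
#' Adds one probabilistic row per requested internal node to an alignment:
#' presence by the two-lineage-direction rule ([infer_presence()]) and
#' posterior base probabilities by pruning ([compute_posteriors()]).
#'
#' @param aln A [prob_alignment] whose extant rows match the tree tips.
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param nodes Internal-node labels to reconstruct (default: all).
#' @return The alignment with the reconstructed rows appended.
#' @export
reconstruct_ancestors <- function(aln, tree, nodes = NULL) {
  codes <- alignment_codes(aln)
  presence <- infer_presence(codes > 0L, tree)
  nodes <- nodes %||% colnames(presence)
  post <- compute_posteriors(codes, tree, nodes)
  rows <- aln$rows
  for (nm in nodes) {
    pr <- post[[nm]]
    pres <- presence[, nm]
    pr[!pres, ] <- NA_real_
    rows[[nm]] <- list(present = pres, probs = pr)
  }
  prob_alignment(rows, reference = aln$reference)
}

# all alignment columns of the extant rows as integer codes
alignment_codes <- function(aln) {
  leaf_rows <- aln$rows[vapply(aln$rows, is.character, logical(1))]
  m <- vapply(leaf_rows, encode_bases, integer(aln$ncol))
  if (is.null(dim(m))) m <- matrix(m, nrow = aln$ncol)
  colnames(m) <- names(leaf_rows)
  m
}

#' Reference-anchored track of a reconstructed node
#'
#' Subsets a node's per-column track to the columns carrying reference
#' bases, so entries line up with 0-based reference offsets.
#'
#' @param aln A [prob_alignment] containing the reconstructed row.
#' @param name Node row name.
#' @return A list with `present` and `probs`, one entry per reference base.
#' @export
ancestor_ref_track <- function(aln, name) {
  tr <- node_track(aln, name)
  cols <- aln$ref_coord_map
  list(present = tr$present[cols], probs = tr$probs[cols, , drop = FALSE])
}

#' Call the ancestral allele from posterior vectors
#'
#' The most probable base when its posterior is at least `cutoff`
#' (default 99%), else `"N"` so that only high-confidence sites feed
#' downstream polarization.
#'
#' @param probs Matrix of posterior vectors (rows sum to 1) or one vector.
#' @param cutoff Minimum posterior for a confident call.
#' @return Character vector of `A/C/G/T/N`.
#' @export
aa_from_posterior <- function(probs, cutoff = 0.99) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  mx <- apply(probs, 1, max)
  arg <- apply(probs, 1, which.max)
  ifelse(is.finite(mx) & mx >= cutoff, BASES[arg], "N")
}

#' Annotate variants with the ancestral allele
#'
#' @param variants Variant tibble with 0-based `pos` (reference offsets).
#' @param ancestor Reference-anchored ancestor track
#'   ([ancestor_ref_track()]).
#' @param cutoff Posterior cutoff for a confident call.
#' @return `variants` with an `aa` column (`"N"` where the ancestor is
#'   absent or uncertain).
#' @export
annotate_ancestral_allele <- function(variants, ancestor, cutoff = 0.99) {
  n_ref <- length(ancestor$present)
  if (any(variants$pos < 0 | variants$pos >= n_ref)) {
    abort("Variant positions outside the reference range.")
  }
  idx <- variants$pos + 1L
  aa <- rep("N", nrow(variants))
  ok <- ancestor$present[idx]
  if (any(ok)) {
    aa[ok] <- aa_from_posterior(ancestor$probs[idx[ok], , drop = FALSE], cutoff)
  }
  variants$aa <- aa
  variants
}

#' Polarize variants against the annotated ancestral allele
#'
#' Drops sites whose ancestral allele is `N` or matches neither observed
#' allele, and computes the derived allele frequency: the frequency of the
#' non-ancestral allele.
#'
#' @param variants Biallelic variant tibble with ref, alt, aa, ac (alternate
#'   allele count) and an (total alleles).
#' @return The retained variants with `derived` and `daf` columns.
#' @export
polarize_variants <- function(variants) {
  if (any(grepl(",", variants$alt, fixed = TRUE))) {
    abort("Multi-allelic records are not supported; retain only biallelic substitution variants.")
  }
  keep <- !is.na(variants$aa) & variants$aa != "N" &
    (variants$aa == variants$ref | variants$aa == variants$alt)
  out <- variants[keep, , drop = FALSE]
  gt <- attr(variants, "gt")
  if (!is.null(gt)) attr(out, "gt") <- gt[keep, , drop = FALSE]
  anc_is_ref <- out$aa == out$ref
  out$derived <- ifelse(anc_is_ref, out$alt, out$ref)
  out$daf <- ifelse(anc_is_ref, out$ac / out$an, 1 - out$ac / out$an)
  out
}

#' Attach a consensus-pair cherry to a tree
#'
#' Replaces one leaf with a two-leaf cherry of negligible branch length
#' (default 1e-8), so that two rows (e.g. a reference sequence and its
#' alternate-allele counterpart) act as an equal-weight consensus haplotype
#' during ancestral inference instead of biasing it toward either row.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaf Existing tip label.
#' @param new_leaf Name of the added sibling row.
#' @param pair_name Label of the new internal (consensus) node.
#' @param eps Branch length of the two cherry edges.
#' @return The modified tree.
#' @export
add_consensus_pair <- function(tree, leaf, new_leaf, pair_name = paste0(leaf, "cons"),
                               eps = 1e-8) {
  if (!leaf %in% tree$tip.label) abort(sprintf("No tip named '%s'.", leaf))
  t_orig <- branch_length(tree, leaf)
  nwk <- ape::write.tree(tree)
  repl <- sprintf("(%s:%.10g,%s:%.10g)%s:", leaf, eps, new_leaf, eps, pair_name)
  # tip labels are unique, so a boundary-anchored replacement is safe
  out <- stringr::str_replace(nwk, stringr::regex(sprintf("(?<![A-Za-z0-9_.-])%s:", leaf)),
                              repl)
  newt <- parse_newick(out)
  stopifnot(all(c(leaf, new_leaf) %in% newt$tip.label))
  # the cherry keeps the original stem length
  bl <- branch_length(newt, pair_name)
  if (!isTRUE(all.equal(bl, t_orig))) warn("Consensus stem length changed unexpectedly.")
  newt
}
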