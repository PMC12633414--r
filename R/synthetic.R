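# Seeded generators reproducing the statistical structure the analysis
# assumes: alignments evolved under a fixed tree with planted accelerated
# windows and deletions, biallelic variants with derived-allele frequencies
# under a scaled selection parameter, and single-cell reporter counts with
# negative-control noise.  Every generator is a pure function of
# (parameters, seed).

# Simulate one chunk of evolution down the tree.  Assumes the RNG state is
# already seeded.  Returns integer base codes and presence flags at the
# leaves (sites x tips).  `extra_len` adds branch length per site on one
# target branch (the planted acceleration).
sim_chunk <- function(ti, S, edge_len, target_id = NA_integer_,
                      extra_mult = NULL, indel_rate = 0.1, indel_mean = 5) {
  codes <- vector("list", ti$n_total)
  pres <- vector("list", ti$n_total)
  codes[[ti$root]] <- sample.int(4L, S, replace = TRUE)
  pres[[ti$root]] <- rep(TRUE, S)
  for (v in ti$preorder) {
    if (v == ti$root) next
    p <- ti$parent[v]
    x <- codes[[p]]
    if (!is.na(target_id) && v == target_id && !is.null(extra_mult)) {
      t_site <- edge_len[v] * extra_mult
      p_change <- 0.75 * (1 - exp(-4 * t_site / 3))
      flip <- which(runif(S) < p_change)
    } else {
      # constant rate: draw the flip count, then the flip positions
      p_change <- 0.75 * (1 - exp(-4 * edge_len[v] / 3))
      n_flip <- rbinom(1L, S, p_change)
      flip <- if (n_flip > 0L) sample.int(S, n_flip) else integer(0)
    }
    if (length(flip)) {
      # a uniformly chosen different base
      x[flip] <- 1L + (x[flip] - 1L + sample.int(3L, length(flip), replace = TRUE)) %% 4L
    }
    pv <- pres[[p]]
    n_del <- rpois(1L, indel_rate * edge_len[v] * S)
    if (n_del > 0L) {
      starts <- sample.int(S, n_del, replace = TRUE)
      lens <- 1L + rgeom(n_del, prob = 1 / indel_mean)
      for (j in seq_len(n_del)) {
        pv[seq.int(starts[j], min(S, starts[j] + lens[j] - 1L))] <- FALSE
      }
    }
    codes[[v]] <- x
    pres[[v]] <- pv
    # free the parent once all its children are done
  }
  tips <- seq_len(ti$n_tip)
  code_m <- vapply(tips, function(v) codes[[v]], integer(S))
  pres_m <- vapply(tips, function(v) pres[[v]], logical(S))
  colnames(code_m) <- colnames(pres_m) <- ti$names[tips]
  code_m[!pres_m] <- 0L
  list(codes = code_m, present = pres_m)
}

#' Simulate an alignment under a fixed tree
#'
#' Evolves a uniform root sequence down the tree under Jukes-Cantor at each
#' branch's length, with optional planted intervals where one target
#' branch's substitution rate is multiplied, and geometric-length deletions
#' (presence toggling) at a rate proportional to branch length.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param length Sequence length in bases.
#' @param planted Optional tibble of non-overlapping intervals start/end
#'   (0-based half-open) with a `multiplier` column (>= 1).
#' @param target_branch Node whose stem branch carries the planted
#'   acceleration.
#' @param indel_rate Deletion events per site per unit branch length.
#' @param indel_mean Mean deletion length (geometric).
#' @param seed Integer seed.
#' @param reference Reference row (default: first tip).
#' @return List: `alignment` (a [prob_alignment] of the leaf rows) and
#'   `truth` (planted intervals, parameters, seed).
#' @export
simulate_alignment <- function(tree, length, planted = NULL,
                               target_branch = NULL, indel_rate = 0.1,
                               indel_mean = 5, seed = 1L,
                               reference = NULL) {
  ti <- tree_index(tree)
  target_id <- NA_integer_
  if (!is.null(planted) && nrow(planted) > 0L) {
    if (is.null(target_branch)) abort("`planted` needs a `target_branch`.")
    target_id <- match(target_branch, ti$names)
    if (is.na(target_id)) abort(sprintf("No node named '%s'.", target_branch))
    if (any(planted$multiplier < 1)) abort("Planted multipliers must be >= 1.")
    if (any(planted$start < 0 | planted$end > length)) {
      abort("Planted intervals must lie within [0, length).")
    }
    pl <- planted[order(planted$start), , drop = FALSE]
    if (nrow(pl) > 1L && any(pl$start[-1] < pl$end[-nrow(pl)])) {
      abort("Planted intervals must not overlap.")
    }
  }
  sim <- with_seed(seed, {
    mult <- rep(1, length)
    if (!is.na(target_id)) {
      for (i in seq_len(nrow(planted))) {
        mult[seq.int(planted$start[i] + 1L, planted$end[i])] <- planted$multiplier[i]
      }
    }
    sim_chunk(ti, length, ti$edge_len, target_id, mult, indel_rate, indel_mean)
  })
  rows <- lapply(seq_len(ti$n_tip), function(j) decode_bases(sim$codes[, j]))
  names(rows) <- ti$names[seq_len(ti$n_tip)]
  reference <- reference %||% names(rows)[1]
  # the reference row must anchor coordinates, so keep it first
  rows <- c(rows[reference], rows[setdiff(names(rows), reference)])
  list(
    alignment = prob_alignment(rows, reference = reference),
    truth = list(planted = planted, target_branch = target_branch,
                 indel_rate = indel_rate, indel_mean = indel_mean, seed = seed)
  )
}

# Up pass + targeted down pass: marginal posteriors at selected internal
# nodes only (memory- and time-light for long chunks).
posterior_at_nodes <- function(ti, codes, edge_len, node_names) {
  ids <- match(node_names, ti$names)
  if (anyNA(ids)) abort("Unknown node name in `node_names`.")
  up <- prune_up(ti, codes, edge_len, scale = FALSE)
  needed <- unique(unlist(lapply(ids, function(v) {
    path <- v
    while (!is.na(ti$parent[path[length(path)]])) {
      path <- c(path, ti$parent[path[length(path)]])
    }
    path
  })))
  S <- nrow(up$L[[ti$root]])
  A <- vector("list", ti$n_total)
  A[[ti$root]] <- matrix(0.25, S, 4L)
  for (v in ti$preorder) {
    kids <- intersect(ti$children[[v]], needed)
    if (length(kids) == 0L || is.null(A[[v]])) next
    for (ch in kids) {
      B <- A[[v]]
      for (sib in setdiff(ti$children[[v]], ch)) B <- B * up$M[[sib]]
      A[[ch]] <- jc_mult(B, edge_len[ch])
    }
  }
  out <- lapply(ids, function(v) {
    post <- A[[v]] * up$L[[v]]
    sums <- rowSums(post)
    sums[sums == 0] <- 1
    post <- post / sums
    colnames(post) <- BASES
    post
  })
  names(out) <- node_names
  out
}

#' Simulate a genome-scale alignment and screen it, in chunks
#'
#' Streams the full pipeline at genome scale without materialising the
#' whole alignment: simulates leaf sequences chunk by chunk under the tree
#' (with planted accelerated windows on a target branch), reconstructs the
#' two internal nodes of interest from the leaves, computes per-column
#' event labels, and runs the calibrated window screen on the concatenated
#' event tracks.  Coordinates are in the root (ancestral) frame.
#'
#' @inheritParams simulate_alignment
#' @param node_a,node_b Internal nodes whose divergence is screened.
#' @param config A [screen_config()].
#' @param chunk_size Columns simulated and reconstructed per chunk.
#' @return List: `screen` (an `aqer_screen`) and `truth`.
#' @export
simulate_divergence_screen <- function(tree, length, planted = NULL,
                                       target_branch = "HUMANanc",
                                       node_a = "hcaT2T", node_b = "HUMANanc",
                                       indel_rate = 0.1, indel_mean = 5,
                                       seed = 1L, config = screen_config(),
                                       chunk_size = 250000L) {
  ti <- tree_index(tree)
  target_id <- match(target_branch, ti$names)
  mult_all <- rep(1, length)
  if (!is.null(planted) && nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      mult_all[seq.int(planted$start[i] + 1L, planted$end[i])] <- planted$multiplier[i]
    }
  }
  sub <- integer(length)
  presA <- logical(length)
  presB <- logical(length)
  with_seed(seed, {
    off <- 0L
    while (off < length) {
      S <- min(chunk_size, length - off)
      idx <- seq.int(off + 1L, off + S)
      sim <- sim_chunk(ti, S, ti$edge_len, target_id, mult_all[idx],
                       indel_rate, indel_mean)
      pres_int <- infer_presence(sim$present, tree)
      post <- posterior_at_nodes(ti, sim$codes, ti$edge_len, c(node_a, node_b))
      pa <- pres_int[, node_a]
      pb <- pres_int[, node_b]
      both <- pa & pb
      d <- rep(NA_real_, S)
      if (any(both)) {
        d[both] <- cosine_distance(post[[node_a]][both, , drop = FALSE],
                                   post[[node_b]][both, , drop = FALSE])
      }
      sub[idx] <- as.integer(both & !is.na(d) & d >= config$cosine_threshold)
      presA[idx] <- pa
      presB[idx] <- pb
      off <- off + S
    }
  })
  one <- xor(presA, presB)
  gap <- integer(length)
  if (any(one)) {
    r <- rle(one)
    ends <- cumsum(r$lengths)
    anchors <- (ends - r$lengths + 1L)[r$values]
    gap[anchors] <- 1L
  }
  ref_ev <- list(sub = sub, gap = gap,
                 callable = as.integer(presA & presB), n_ref = length)
  screen <- screen_from_ref_events(ref_ev, config, chrom = "sim")
  list(
    screen = screen,
    truth = list(planted = planted, target_branch = target_branch,
                 node_a = node_a, node_b = node_b, indel_rate = indel_rate,
                 indel_mean = indel_mean, seed = seed)
  )
}

#' Evenly spaced planted accelerated windows
#'
#' Lays `n` windows of `width` bases at evenly spaced positions, all with
#' the same rate multiplier on the target branch.
#'
#' @param n Number of windows.
#' @param length Genome length.
#' @param width Window width.
#' @param multiplier Branch-length multiplier inside the windows.
#' @return Planted-interval tibble for [simulate_alignment()].
#' @export
planted_windows <- function(n, length, width = 500L, multiplier = 14) {
  anchors <- floor(seq(length / (n + 1), length * n / (n + 1), length.out = n))
  tibble(start = as.integer(anchors), end = as.integer(anchors + width),
         multiplier = multiplier)
}

#' Simulate biallelic variants under a scaled selection parameter
#'
#' Derived-allele counts are drawn from the discretised Wright-Fisher
#' stationary density `f(x) ~ (1 - exp(-g (1 - x))) / ((1 - exp(-g)) x (1 - x))`
#' for selection parameter `g != 0`, and the neutral `f(x) ~ 1/x` for
#' `g = 0`, over frequencies `x = i / n_alleles`, `i = 1..n_alleles - 1`.
#' Positions are uniform within the region set.
#'
#' @param n_sites Number of segregating sites.
#' @param gamma Scaled selection parameter (|gamma| <= 100).
#' @param n_alleles Haploid sample size (alleles per site).
#' @param region Interval tibble the sites are placed in.
#' @param seed Integer seed.
#' @return Variant tibble: chrom, pos, ref, alt, aa, ac, an, daf (ancestral
#'   allele = ref; alt is the derived allele).
#' @export
simulate_variants <- function(n_sites, gamma = 0, n_alleles = 1002L,
                              region = tibble(chrom = "sim", start = 0L, end = 1000000L),
                              seed = 1L) {
  if (n_sites < 1L) abort("`n_sites` must be at least 1.")
  if (abs(gamma) > 100) abort("|gamma| > 100 is outside the numerical guard.")
  n <- as.integer(n_alleles)
  i <- seq_len(n - 1L)
  x <- i / n
  w <- if (gamma == 0) 1 / x else {
    (1 - exp(-gamma * (1 - x))) / ((1 - exp(-gamma)) * x * (1 - x))
  }
  region <- merge_intervals(region)
  sizes <- region$end - region$start
  capacity <- sum(as.numeric(sizes))
  if (capacity < n_sites) abort("Region capacity below `n_sites`.")
  with_seed(seed, {
    counts <- sample(i, n_sites, replace = TRUE, prob = w)
    offs <- sample(capacity, n_sites)   # global offsets, unique
    cum <- cumsum(as.numeric(sizes))
    blk <- findInterval(offs - 1, cum) + 1L
    pos <- as.integer(region$start[blk] + (offs - 1) - c(0, cum)[blk])
    ref <- sample(BASES, n_sites, replace = TRUE)
    alt_shift <- sample.int(3L, n_sites, replace = TRUE)
    alt <- BASES[1L + (match(ref, BASES) - 1L + alt_shift) %% 4L]
    out <- tibble(
      chrom = region$chrom[blk], pos = pos, ref = ref, alt = alt,
      aa = ref, ac = as.integer(counts), an = n,
      derived = alt, daf = counts / n
    )
    arrange(out, .data$chrom, .data$pos)
  })
}

#' Simulate single-cell STARR-seq counts
#'
#' Input library counts are lognormal; per-cell output UMI counts are
#' negative binomial with mean proportional to the construct's input share
#' times its fold effect.  Negative controls have fold effect 1.
#'
#' @param n_constructs Number of constructs (ids `c01`, `c02`, ...).
#' @param active Tibble of construct, fold (>= 1) for planted actives.
#' @param n_cells Number of cells.
#' @param nc_ids Negative-control construct ids (fold forced to 1).
#' @param base_mean Mean output UMIs per cell for a construct of average
#'   input and fold 1.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return List: `counts` (construct, cell, count), `input` (construct,
#'   input_count), `cells`, `truth`.
#' @export
simulate_starr_counts <- function(n_constructs = 20L, active = NULL,
                                  n_cells = 500L, nc_ids = NULL,
                                  base_mean = 0.2, dispersion = 2,
                                  seed = 1L) {
  ids <- sprintf("c%02d", seq_len(n_constructs))
  nc_ids <- nc_ids %||% head(ids, 4L)
  if (!all(nc_ids %in% ids)) abort("`nc_ids` must be a subset of the constructs.")
  fold <- setNames(rep(1, n_constructs), ids)
  if (!is.null(active) && nrow(active) > 0L) {
    if (any(active$fold < 1)) abort("Fold effects must be >= 1.")
    if (any(active$construct %in% nc_ids)) abort("Negative controls cannot be active.")
    fold[active$construct] <- active$fold
  }
  cells <- sprintf("cell%05d", seq_len(n_cells))
  with_seed(seed, {
    input <- rlnorm(n_constructs, meanlog = log(100), sdlog = 0.4)
    mu <- base_mean * fold * input / mean(input)
    counts <- tibble(
      construct = rep(ids, each = n_cells),
      cell = rep(cells, times = n_constructs),
      count = rnbinom(n_constructs * n_cells,
                      mu = rep(mu, each = n_cells), size = dispersion)
    )
    list(
      counts = filter(counts, .data$count > 0L),
      input = tibble(construct = ids, input_count = input),
      cells = cells,
      truth = list(fold = fold, nc_ids = nc_ids, seed = seed)
    )
  })
}
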