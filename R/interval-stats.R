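# Interval arithmetic on tidy tables (0-based half-open), the two-sided
# binomial overlap-enrichment framework, the RAND region simulator, and
# GC-content classification.  IRanges does the set algebra; the placement
# null is the package's own model.

split_iranges <- function(x) {
  lapply(split(x, x$chrom), function(s) {
    IRanges::IRanges(start = s$start + 1L, end = s$end)
  })
}

iranges_to_tbl <- function(irl) {
  out <- lapply(names(irl), function(ch) {
    ir <- irl[[ch]]
    if (length(ir) == 0L) return(NULL)
    tibble(chrom = ch, start = as.integer(IRanges::start(ir)) - 1L,
           end = as.integer(IRanges::end(ir)))
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  arrange(res, .data$chrom, .data$start, .data$end)
}

#' Merge overlapping or book-ended intervals
#'
#' @param x Interval tibble (chrom/start/end).
#' @return Disjoint, sorted intervals.
#' @export
merge_intervals <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0L) return(x[c("chrom", "start", "end")])
  iranges_to_tbl(lapply(split_iranges(x), IRanges::reduce))
}

#' Subtract one interval set from another
#'
#' Removes every base of `b` from `a`, splitting intervals as needed.
#'
#' @param a,b Interval tibbles.
#' @return Merged intervals covering `a` minus `b`.
#' @export
subtract_intervals <- function(a, b) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  a_ir <- lapply(split_iranges(a), IRanges::reduce)
  b_ir <- lapply(split_iranges(b), IRanges::reduce)
  out <- lapply(names(a_ir), function(ch) {
    if (ch %in% names(b_ir)) {
      IRanges::setdiff(a_ir[[ch]], b_ir[[ch]])
    } else {
      a_ir[[ch]]
    }
  })
  names(out) <- names(a_ir)
  iranges_to_tbl(out)
}

#' Count elements of one set overlapping another
#'
#' Half-open semantics; each element of `a` is counted at most once.
#'
#' @param a,b Interval tibbles.
#' @param per_element Return the per-element 0/1 indicator instead of the
#'   total.
#' @return Integer count (or indicator vector).
#' @export
count_overlaps <- function(a, b, per_element = FALSE) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  hit <- integer(nrow(a))
  if (nrow(a) > 0L && nrow(b) > 0L) {
    b_ir <- lapply(split_iranges(b), IRanges::reduce)
    for (ch in unique(a$chrom)) {
      sel <- which(a$chrom == ch)
      if (!ch %in% names(b_ir)) next
      ir <- IRanges::IRanges(start = a$start[sel] + 1L, end = a$end[sel])
      hit[sel] <- as.integer(IRanges::overlapsAny(ir, b_ir[[ch]]))
    }
  }
  if (per_element) hit else sum(hit)
}

# Background blocks: per-chromosome spans minus the excluded set.
background_blocks <- function(genome, excluded = NULL) {
  if (!all(c("chrom", "size") %in% names(genome))) {
    abort("`genome` must have chrom and size columns.")
  }
  bg <- tibble(chrom = genome$chrom, start = 0L, end = as.integer(genome$size))
  if (!is.null(excluded) && nrow(excluded) > 0L) {
    bg <- subtract_intervals(bg, excluded)
  }
  bg
}

# Per-element success probability that a uniformly placed element of length
# w (within the background blocks, not crossing block boundaries) overlaps
# at least one base of the merged annotation b.
placement_probs <- function(widths, blocks, b_merged) {
  total_starts <- function(w) sum(pmax(0, (blocks$end - blocks$start) - w + 1))
  vapply(widths, function(w) {
    T_w <- total_starts(w)
    if (T_w <= 0) abort("Element longer than any background block.")
    if (nrow(b_merged) == 0L) return(0)
    hits <- 0
    for (i in seq_len(nrow(blocks))) {
      ch <- blocks$chrom[i]
      lo_blk <- blocks$start[i]; hi_blk <- blocks$end[i] - w
      if (hi_blk < lo_blk) next
      bb <- b_merged[b_merged$chrom == ch, , drop = FALSE]
      if (nrow(bb) == 0L) next
      lo <- pmax(lo_blk, bb$start - w + 1)
      hi <- pmin(hi_blk, bb$end - 1)
      len <- pmax(0, hi - lo + 1)
      # overlapping b-blocks could double count starts; merge the start ranges
      if (any(len > 0)) {
        rng <- IRanges::reduce(IRanges::IRanges(start = lo[len > 0] + 1L,
                                                end = hi[len > 0] + 1L))
        hits <- hits + sum(IRanges::width(rng))
      }
    }
    min(1, hits / T_w)
  }, numeric(1))
}

# Exact Poisson-binomial probability mass by dynamic-programming
# convolution.
poisson_binomial_pmf <- function(p) {
  f <- 1
  for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  f
}

#' Overlap enrichment with a Poisson-binomial placement null
#'
#' Models each element of `a` as independently and uniformly placed (with
#' its own length) within the background (genome minus `excluded`), never
#' crossing a background block boundary.  The per-element probability of
#' touching the merged annotation `b` gives a Poisson-binomial null for the
#' observed overlap count: exact by convolution up to `exact_max` elements,
#' normal approximation beyond.  The two-sided p-value is twice the smaller
#' tail, capped at 1.
#'
#' @param a Query interval tibble.
#' @param b Annotation interval tibble (merged internally).
#' @param genome Tibble of chrom/size.
#' @param excluded Optional intervals removed from the placeable background.
#' @param exact_max Largest query size for the exact convolution.
#' @return One-row tibble: n_elements, observed, expected, ratio, p_two,
#'   direction.
#' @export
overlap_enrichment <- function(a, b, genome, excluded = NULL,
                               exact_max = 5000L) {
  check_intervals(a, "a")
  if (nrow(a) == 0L) abort("`a` must be non-empty.")
  b_merged <- merge_intervals(b)
  blocks <- background_blocks(genome, excluded)
  widths <- a$end - a$start
  p_i <- placement_probs(widths, blocks, b_merged)
  expected <- sum(p_i)
  observed <- count_overlaps(a, b_merged)
  if (expected == 0) {
    return(tibble(n_elements = nrow(a), observed = observed, expected = 0,
                  ratio = NA_real_, p_two = 1,
                  direction = if (observed > 0) "enriched" else "undefined"))
  }
  if (nrow(a) <= exact_max) {
    pmf <- poisson_binomial_pmf(p_i)
    tail_ge <- sum(pmf[(observed + 1L):length(pmf)])
    tail_le <- sum(pmf[1:(observed + 1L)])
  } else {
    mu <- expected
    sdv <- sqrt(sum(p_i * (1 - p_i)))
    tail_ge <- pnorm(observed - 0.5, mu, sdv, lower.tail = FALSE)
    tail_le <- pnorm(observed + 0.5, mu, sdv)
  }
  p_two <- min(1, 2 * min(tail_ge, tail_le))
  tibble(
    n_elements = nrow(a), observed = observed, expected = expected,
    ratio = observed / expected, p_two = p_two,
    direction = if (observed >= expected) "enriched" else "depleted"
  )
}

#' Adjust a table of enrichment results for multiple testing
#'
#' @param results Tibble with a `p_two` column (one row per tested
#'   annotation).
#' @param method `"bonferroni"` (default) or `"BH"` (FDR, e.g. for GWAS
#'   trait scans).
#' @return `results` with an `adj_p` column.
#' @export
adjust_enrichments <- function(results, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  results$adj_p <- p.adjust(results$p_two, method = method)
  results
}

#' Simulate matched pseudorandom control regions
#'
#' Draws `n` non-overlapping elements of fixed length `round(mean_len)`
#' uniformly from the background blocks (never crossing a block boundary),
#' reproducibly for a given seed — the RAND construction used as a neutral
#' proxy for a region set with the same element count and mean length.
#'
#' @param background Interval tibble of allowed blocks.
#' @param n Number of elements.
#' @param mean_len Mean element length (rounded to the common length).
#' @param seed Integer seed.
#' @param max_attempts Sampling attempts before giving up.
#' @return Interval tibble of `n` regions.
#' @export
simulate_rand_regions <- function(background, n, mean_len, seed,
                                  max_attempts = 10000L) {
  bg <- merge_intervals(background)
  len <- as.integer(round(mean_len))
  if (len < 1L) abort("`mean_len` must round to at least 1.")
  starts_per_block <- pmax(0L, (bg$end - bg$start) - len + 1L)
  total <- sum(as.numeric(starts_per_block))
  if (total < n) abort("Insufficient background capacity for the requested regions.")
  cum <- cumsum(as.numeric(starts_per_block))
  with_seed(seed, {
    chosen <- vector("list", n)
    got <- 0L
    for (attempt in seq_len(max_attempts)) {
      if (got >= n) break
      u <- floor(runif(1, 0, total))
      blk <- findInterval(u, cum) + 1L
      off <- u - c(0, cum)[blk]
      s <- bg$start[blk] + off
      cand <- c(chrom = bg$chrom[blk], start = s, end = s + len)
      clash <- FALSE
      for (j in seq_len(got)) {
        prev <- chosen[[j]]
        if (prev$chrom == bg$chrom[blk] && s < prev$end && prev$start < s + len) {
          clash <- TRUE; break
        }
      }
      if (!clash) {
        got <- got + 1L
        chosen[[got]] <- tibble(chrom = bg$chrom[blk], start = as.integer(s),
                                end = as.integer(s + len))
      }
    }
    if (got < n) abort("Could not place all regions without overlap; background too tight.")
    arrange(bind_rows(chosen), .data$chrom, .data$start)
  })
}

#' GC content and class of sequences
#'
#' Fraction `(G+C)/(A+C+G+T)` with Ns excluded from the denominator;
#' classes follow the GC-rich (> 0.75) / GC-poor (< 0.25) convention.
#'
#' @param seqs Character vector of sequences.
#' @param rich,poor Class cutoffs.
#' @return Tibble with gc and class (`rich`/`mid`/`poor`); all-N sequences
#'   are returned as NA with a warning.
#' @export
gc_content <- function(seqs, rich = 0.75, poor = 0.25) {
  counts <- function(s, letters) {
    v <- strsplit(toupper(s), "")[[1]]
    sum(v %in% letters)
  }
  gc <- vapply(seqs, function(s) {
    num <- counts(s, c("G", "C"))
    den <- counts(s, BASES)
    if (den == 0) NA_real_ else num / den
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(gc)) warn("Dropped GC fraction for sequence(s) with no A/C/G/T bases.")
  cls <- rep(NA_character_, length(gc))
  cls[!is.na(gc) & gc > rich] <- "rich"
  cls[!is.na(gc) & gc < poor] <- "poor"
  cls[!is.na(gc) & is.na(cls)] <- "mid"
  tibble(gc = gc, class = cls)
}

#' Chi-squared test of a GC class against the genome background
#'
#' Builds the 2x2 contingency table \{set, genome\} x \{in-class,
#' not-in-class\} and applies Pearson's chi-squared test without
#' continuity correction.
#'
#' @param set_classes,genome_classes Class vectors from [gc_content()].
#' @param which `"rich"` or `"poor"`.
#' @return Tibble with statistic and p.value.
#' @export
gc_enrichment_test <- function(set_classes, genome_classes, which = c("rich", "poor")) {
  which <- match.arg(which)
  tab <- rbind(
    c(sum(set_classes == which, na.rm = TRUE),
      sum(set_classes != which, na.rm = TRUE)),
    c(sum(genome_classes == which, na.rm = TRUE),
      sum(genome_classes != which, na.rm = TRUE))
  )
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ht$statistic), p.value = unname(ht$p.value))
}

#' Filter intervals by a posterior-probability track
#'
#' Keeps intervals whose posterior value reaches the cutoff (inclusive),
#' e.g. hidden-state posteriors ahead of an overlap-enrichment test.
#'
#' @param track Interval tibble with a `value` column in \[0, 1\].
#' @param cutoff Minimum value retained.
#' @return The retained intervals.
#' @export
posterior_filter <- function(track, cutoff) {
  if (!"value" %in% names(track)) abort("`track` needs a `value` column.")
  if (any(track$value < 0 | track$value > 1, na.rm = TRUE)) {
    abort("Posterior values must lie in [0, 1].")
  }
  track[!is.na(track$value) & track$value >= cutoff, , drop = FALSE]
}
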