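# Population-genetic evidence layer: divergent-site extraction, the
# fixed/polymorphic partition with chi-squared tests, allele frequency
# spectra with proximity blocking, reversion-candidate classification, and
# per-element signal comparisons.

#' Extract divergent substitution sites between two nodes
#'
#' One site per substitution column (cosine distance at or above the
#' screen threshold), mapped to 0-based reference coordinates; gap events
#' are excluded so uneven gap sizes cannot skew site counts.
#'
#' @param aln A [prob_alignment] with both node rows.
#' @param node_a,node_b Row names.
#' @param config A [screen_config()].
#' @param chrom Chromosome name recorded in the output.
#' @return Tibble of 1-base intervals: chrom, start, end.
#' @export
extract_divergent_sites <- function(aln, node_a, node_b,
                                    config = screen_config(), chrom = "ref") {
  ta <- node_track(aln, node_a)
  tb <- node_track(aln, node_b)
  ev <- call_site_events(ta, tb, config)
  sub_cols <- which(ev$label == "substitution")
  # only columns that carry a reference base have a 1-base site coordinate
  on_ref <- sub_cols %in% aln$ref_coord_map
  pos <- match(sub_cols[on_ref], aln$ref_coord_map) - 1L
  tibble(chrom = chrom, start = pos, end = pos + 1L)
}

#' Partition divergent sites into fixed and polymorphic
#'
#' Divergent sites observed as polymorphic in the population sample are
#' labelled `polymorphic`; the rest are `fixed` (no observed polymorphism).
#'
#' @param div_sites Divergent-site tibble (1-base intervals).
#' @param variants Variant tibble with 0-based `pos` (and `chrom`).
#' @return `div_sites` with a `status` column.
#' @export
partition_fixed_polymorphic <- function(div_sites, variants) {
  key_site <- paste(div_sites$chrom, div_sites$start)
  key_var <- paste(variants$chrom %||% "ref", variants$pos)
  div_sites$status <- ifelse(key_site %in% key_var, "polymorphic", "fixed")
  div_sites
}

#' Chi-squared test of fixed/polymorphic proportions against a reference
#'
#' Pearson chi-squared test of independence (df = 1, no continuity
#' correction) on the 2x2 table \{set, reference\} x \{fixed,
#' polymorphic\}, plus per-base densities when set lengths are supplied.
#'
#' @param set_status,ref_status `status` vectors from
#'   [partition_fixed_polymorphic()].
#' @param set_bases,ref_bases Optional total base counts of the two region
#'   sets, for divergent- and polymorphic-sites-per-base densities.
#' @return One-row tibble: counts, polymorphic proportions, statistic,
#'   p.value, and densities when computable.
#' @export
fixed_poly_test <- function(set_status, ref_status,
                            set_bases = NA_real_, ref_bases = NA_real_) {
  tab <- rbind(
    c(sum(set_status == "fixed"), sum(set_status == "polymorphic")),
    c(sum(ref_status == "fixed"), sum(ref_status == "polymorphic"))
  )
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    abort("A chi-squared expected cell is zero; use an exact test instead.")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(
    set_fixed = tab[1, 1], set_polymorphic = tab[1, 2],
    ref_fixed = tab[2, 1], ref_polymorphic = tab[2, 2],
    set_poly_prop = tab[1, 2] / sum(tab[1, ]),
    ref_poly_prop = tab[2, 2] / sum(tab[2, ]),
    statistic = unname(ht$statistic), p.value = unname(ht$p.value),
    set_div_per_base = sum(tab[1, ]) / set_bases,
    set_poly_per_base = tab[1, 2] / set_bases,
    ref_div_per_base = sum(tab[2, ]) / ref_bases,
    ref_poly_per_base = tab[2, 2] / ref_bases
  )
}

#' Thin variants so retained sites are far apart
#'
#' Greedy proximity blocking in a seeded shuffle order: a variant is kept
#' iff it lies at least `min_dist` bases from every already-retained
#' variant on the same chromosome.  Reduces linkage effects on the allele
#' frequency spectrum; deterministic given the seed.
#'
#' @param variants Variant tibble with `pos` (and optionally `chrom`).
#' @param min_dist Minimum pairwise distance in bases.
#' @param seed Integer seed for the acceptance order.
#' @return The retained subset, in original row order.
#' @export
proximity_block <- function(variants, min_dist = 10000L, seed = 10L) {
  n <- nrow(variants)
  if (n <= 1L) return(variants)
  chrom <- variants$chrom %||% rep("ref", n)
  pos <- variants$pos
  ord <- with_seed(seed, sample.int(n))
  keep <- logical(n)
  kept_pos <- split(numeric(0), character(0))
  for (i in ord) {
    ch <- chrom[i]
    prev <- kept_pos[[ch]]
    if (is.null(prev) || all(abs(prev - pos[i]) >= min_dist)) {
      keep[i] <- TRUE
      kept_pos[[ch]] <- c(prev, pos[i])
    }
  }
  variants[keep, , drop = FALSE]
}

#' Allele frequency spectrum
#'
#' Polarized: counts of sites per derived allele count `1..n-1` (derived
#' allele frequency, DAF).  Unpolarized: the same classes folded onto the
#' minor allele, MAF in `(0, 0.5]`.
#'
#' @param variants Variant tibble.  Polarized mode needs `daf` and `an`;
#'   unpolarized needs `ac` and `an`.
#' @param polarized Whether the spectrum is on derived (TRUE) or minor
#'   (FALSE) allele counts.
#' @return Tibble: allele count class `i`, its frequency `freq`, and the
#'   site count.
#' @export
allele_frequency_spectrum <- function(variants, polarized = TRUE) {
  n <- unique(variants$an)
  if (length(n) != 1L) abort("All sites must share the same total allele count.")
  if (polarized) {
    if (!"daf" %in% names(variants)) abort("Polarized spectrum needs a `daf` column.")
    counts <- round(variants$daf * n)
  } else {
    if (!"ac" %in% names(variants) || anyNA(variants$ac)) {
      abort("Unpolarized spectrum needs allele counts (`ac`).")
    }
    counts <- pmin(variants$ac, n - variants$ac)
  }
  counts <- counts[counts >= 1 & counts <= n - 1]
  classes <- if (polarized) seq_len(n - 1L) else seq_len(floor(n / 2))
  tibble(
    i = classes,
    freq = classes / n,
    count = as.integer(tabulate(counts, nbins = max(classes))[classes])
  )
}

#' Fold a polarized spectrum onto minor allele classes
#'
#' @param spectrum Polarized spectrum from [allele_frequency_spectrum()].
#' @param n Total allele count.
#' @return Folded (MAF) spectrum.
#' @export
fold_spectrum <- function(spectrum, n) {
  folded_class <- pmin(spectrum$i, n - spectrum$i)
  agg <- rowsum(spectrum$count, folded_class)
  classes <- as.integer(rownames(agg))
  tibble(i = classes, freq = classes / n, count = as.integer(agg[, 1]))
}

#' Plot an allele frequency spectrum
#'
#' @param spectrum Spectrum tibble, optionally with a `set` column for
#'   overlays.
#' @param bins Number of frequency bins for display.
#' @return A ggplot object.
#' @export
plot_afs <- function(spectrum, bins = 20L) {
  spectrum$bin <- cut(spectrum$freq, breaks = seq(0, 1, length.out = bins + 1L),
                      include.lowest = TRUE)
  agg <- spectrum |>
    group_by(across(any_of(c("set", "bin")))) |>
    summarise(count = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "allele frequency", y = "sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Classify a high-frequency derived polymorphic divergent site
#'
#' For a polymorphic divergent site with derived allele frequency above
#' 0.95, inspects the haplotypes still carrying the ancestral allele: if
#' any of them also carries the ancestral allele at another divergent site
#' within `context_w` bases, the site looks like an incompletely swept
#' ancestral haplotype; otherwise it is a reversion candidate
#' (back-mutation after ancient fixation).
#'
#' @param focal Index (row) of the focal site in `variants`.
#' @param variants Variant tibble with `pos` and `daf`, carrying the
#'   haplotype matrix (sites x haplotypes, 1 = derived, 0 = ancestral) as
#'   attribute `"gt"` or passed via `gt`.
#' @param divergent Logical vector flagging which rows are divergent sites.
#' @param context_w Haplotype context window in bases.
#' @param daf_cutoff Minimum derived allele frequency.
#' @param gt Haplotype matrix override.
#' @return One of `"not_applicable"`, `"ancestral_haplotype"`,
#'   `"reversion_candidate"`.
#' @export
classify_high_daf_site <- function(focal, variants, divergent,
                                   context_w = 2000L, daf_cutoff = 0.95,
                                   gt = attr(variants, "gt")) {
  if (is.null(gt)) abort("Phased haplotypes (`gt`) are required.")
  daf <- variants$daf[focal]
  if (daf <= daf_cutoff) return("not_applicable")
  carriers <- which(gt[focal, ] == 0L)
  if (length(carriers) == 0L) {
    if (daf < 1) abort("No ancestral-allele carrier found despite DAF < 1; inconsistent data.")
    return("not_applicable")
  }
  nearby <- which(divergent &
                    abs(variants$pos - variants$pos[focal]) <= context_w &
                    seq_len(nrow(variants)) != focal)
  if (length(nearby)) {
    ctx <- gt[nearby, carriers, drop = FALSE]
    if (any(ctx == 0L, na.rm = TRUE)) return("ancestral_haplotype")
  }
  "reversion_candidate"
}

#' Mean per-element signal with tests against a reference set
#'
#' Averages a per-position signal (e.g. total mutation-rate estimates,
#' already summed over the three possible substitutions) over the
#' positions covered by each element; elements with no covered position
#' are dropped and counted.  Each element set is compared to the reference
#' set by a Welch two-sample t-test, Bonferroni-adjusted across sets.
#'
#' @param element_sets Named list of interval tibbles.
#' @param signal Tibble with chrom, pos (0-based) and `value`.
#' @param reference Name of the reference set within `element_sets`.
#' @return List with `means` (per-element tibble) and `tests` (per-set
#'   tibble with mean difference, p.value, adj_p, n_dropped).
#' @export
mean_signal_per_element <- function(element_sets, signal, reference) {
  if (!reference %in% names(element_sets)) abort("`reference` must name an element set.")
  per_set <- lapply(names(element_sets), function(nm) {
    els <- element_sets[[nm]]
    means <- rep(NA_real_, nrow(els))
    for (i in seq_len(nrow(els))) {
      sel <- signal$chrom == els$chrom[i] &
        signal$pos >= els$start[i] & signal$pos < els$end[i]
      if (any(sel)) means[i] <- mean(signal$value[sel])
    }
    tibble(set = nm, element = seq_len(nrow(els)), mean_signal = means)
  })
  means <- bind_rows(per_set)
  if (all(is.na(means$mean_signal))) abort("No element in any set overlaps the signal track.")
  ref_vals <- means$mean_signal[means$set == reference]
  ref_vals <- ref_vals[!is.na(ref_vals)]
  others <- setdiff(names(element_sets), reference)
  tests <- lapply(others, function(nm) {
    vals <- means$mean_signal[means$set == nm]
    dropped <- sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    p <- if (length(vals) >= 2L && length(ref_vals) >= 2L && sd(c(vals, ref_vals)) > 0) {
      t.test(vals, ref_vals)$p.value
    } else NA_real_
    tibble(set = nm, mean = mean(vals), ref_mean = mean(ref_vals),
           p.value = p, n_dropped = dropped)
  })
  tests <- bind_rows(tests)
  tests$adj_p <- p.adjust(tests$p.value, method = "bonferroni")
  list(means = means[!is.na(means$mean_signal), , drop = FALSE], tests = tests)
}
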