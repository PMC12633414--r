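# The window scan for rapidly diverged regions: per-column event calling
# between two reconstructed nodes, window counts on reference coordinates,
# conservative rate calibration, binomial/BH significance, merged calls.

#' Screen configuration
#'
#' @param window_length Window size in reference bases.
#' @param window_step Step between window starts (1 = maximal sliding;
#'   `window_length` = non-overlapping tiling).
#' @param cosine_threshold Cosine-distance cutoff above which a column is a
#'   substitution event.
#' @param calibration_window Width of the non-overlapping calibration
#'   windows whose maximum event rate is the conservative expected rate.
#' @param alpha_adj Adjusted-p cutoff for calling a window diverged.
#' @param lineage_scale Multiplier applied to the calibrated rate (see
#'   [scale_rate_for_lineage()]).
#' @param min_callable_fraction Calibration windows with a smaller callable
#'   fraction are ignored.
#' @return A `screen_config` list.
#' @export
screen_config <- function(window_length = 500L, window_step = 1L,
                          cosine_threshold = 0.8, calibration_window = 1e7,
                          alpha_adj = 3e-7, lineage_scale = 1,
                          min_callable_fraction = 0.5) {
  if (cosine_threshold <= 0 || cosine_threshold > 1) abort("cosine_threshold must be in (0, 1].")
  if (window_length < 25L) abort("window_length must be >= 25 bases.")
  if (calibration_window < window_length) abort("calibration_window must be >= window_length.")
  if (alpha_adj <= 0 || alpha_adj >= 1) abort("alpha_adj must be in (0, 1).")
  if (window_step < 1L) abort("window_step must be >= 1.")
  structure(list(
    window_length = as.integer(window_length), window_step = as.integer(window_step),
    cosine_threshold = cosine_threshold, calibration_window = calibration_window,
    alpha_adj = alpha_adj, lineage_scale = lineage_scale,
    min_callable_fraction = min_callable_fraction
  ), class = "screen_config")
}

# rowwise cosine distance between two 4-column probability matrices
cosine_distance <- function(u, v) {
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  if (any(nu == 0, na.rm = TRUE) || any(nv == 0, na.rm = TRUE)) {
    abort("Zero-magnitude probability vector.")
  }
  1 - rowSums(u * v) / (nu * nv)
}

#' Call per-column divergence events between two node tracks
#'
#' Where both nodes carry a base, the cosine distance
#' `1 - (u . v) / (|u||v|)` between their posterior vectors approximates
#' the probability that a substitution occurred on the branch separating
#' them; columns at or above `cosine_threshold` are substitution events.
#' A maximal run of columns where exactly one node carries a base is a
#' single gap event, whatever its length, anchored at its first column.
#'
#' @param track_a,track_b Node tracks (lists with `present` and `probs`,
#'   see [node_track()]) over the same columns.
#' @param config A [screen_config()].
#' @return List with `label` (factor: none/substitution/in_gap_event per
#'   column), `distance` (cosine distance, NA unless both present), and
#'   `gap_anchors` (1-based first columns of gap events).
#' @export
call_site_events <- function(track_a, track_b, config = screen_config()) {
  if (length(track_a$present) != length(track_b$present)) {
    abort("Tracks must cover the same columns.")
  }
  n <- length(track_a$present)
  both <- track_a$present & track_b$present
  one <- xor(track_a$present, track_b$present)
  d <- rep(NA_real_, n)
  if (any(both)) {
    d[both] <- cosine_distance(track_a$probs[both, , drop = FALSE],
                               track_b$probs[both, , drop = FALSE])
  }
  lab <- rep("none", n)
  lab[both & !is.na(d) & d >= config$cosine_threshold] <- "substitution"
  lab[one] <- "in_gap_event"
  anchors <- integer(0)
  if (any(one)) {
    r <- rle(one)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    anchors <- starts[r$values]
  }
  list(label = factor(lab, levels = c("none", "substitution", "in_gap_event")),
       distance = d, gap_anchors = anchors)
}

# Map alignment columns to 0-based reference positions: each column is
# attributed to the reference base at or before it (insertions inside a
# window span count toward that window).
columns_to_ref <- function(cols, ref_map) {
  idx <- findInterval(cols, ref_map)
  idx[idx < 1L] <- 1L
  idx - 1L   # 0-based
}

# Per-reference-position event arrays from a column-level event call.
events_to_ref <- function(events, ref_map, track_a, track_b) {
  n_ref <- length(ref_map)
  sub_cols <- which(events$label == "substitution")
  sub <- tabulate(columns_to_ref(sub_cols, ref_map) + 1L, nbins = n_ref)
  gap <- tabulate(columns_to_ref(events$gap_anchors, ref_map) + 1L, nbins = n_ref)
  callable <- as.integer(track_a$present[ref_map] & track_b$present[ref_map])
  list(sub = sub, gap = gap, callable = callable, n_ref = n_ref)
}

# sliding-window sums of a per-position vector via cumulative sums
window_sums <- function(x, L, starts) {
  cs <- c(0, cumsum(x))
  cs[starts + L + 1L] - cs[starts + 1L]
}

#' Count divergence events in sliding windows
#'
#' Lays windows of `window_length` on reference coordinates (step
#' `window_step`) and counts substitution columns, gap-event anchors, and
#' callable reference bases (both nodes present) in each span.
#'
#' @param ref_events Per-position arrays from an event call (internal
#'   layout; produced by [aqer_screen()] or [events_to_ref]).
#' @param config A [screen_config()].
#' @param width Override the window width (used for calibration tiles).
#' @param step Override the step.
#' @param chrom Chromosome name recorded in the output.
#' @return Tibble of windows: chrom, start, end, k_s, k_g, k, callable.
#' @export
windowed_event_counts <- function(ref_events, config = screen_config(),
                                  width = NULL, step = NULL, chrom = "ref") {
  L <- as.integer(width %||% config$window_length)
  s <- as.integer(step %||% config$window_step)
  n <- ref_events$n_ref
  truncated <- FALSE
  if (n < L) {
    warn("Window extends past the chromosome end; truncated.")
    L <- n
    truncated <- TRUE
  }
  starts <- seq.int(0L, n - L, by = s)
  k_s <- window_sums(ref_events$sub, L, starts)
  k_g <- window_sums(ref_events$gap, L, starts)
  callable <- window_sums(ref_events$callable, L, starts)
  tibble(chrom = chrom, start = starts, end = starts + L,
         k_s = as.integer(k_s), k_g = as.integer(k_g),
         k = as.integer(k_s + k_g), callable = as.integer(callable),
         truncated = truncated)
}

#' Conservative expected event rate from wide calibration windows
#'
#' The expected divergence rate is the maximum per-callable-base event rate
#' over non-overlapping wide windows (default 10 Mbp), restricted to
#' windows with a sufficient callable fraction.
#'
#' @param windows Window tibble at calibration width (from
#'   [windowed_event_counts()]).
#' @param config A [screen_config()].
#' @return The calibrated rate (events per callable base).
#' @export
calibrate_expected_rate <- function(windows, config = screen_config()) {
  frac <- windows$callable / (windows$end - windows$start)
  ok <- frac >= config$min_callable_fraction & windows$callable > 0
  if (!any(ok)) abort("No calibration window with sufficient callable fraction.")
  max(windows$k[ok] / windows$callable[ok])
}

#' Scale the calibrated rate to another lineage
#'
#' Multiplies the conservative human-branch rate by the ratio of the
#' lineage's stem branch length to the human stem branch length, both from
#' the neutral tree.
#'
#' @param rate Calibrated rate.
#' @param tree Neutral tree with branch lengths.
#' @param lineage_branch Node name of the target lineage's stem branch.
#' @param human_branch Node name of the human stem branch.
#' @return Scaled rate.
#' @export
scale_rate_for_lineage <- function(rate, tree, lineage_branch,
                                   human_branch = "HUMANanc") {
  t_l <- branch_length(tree, lineage_branch)
  t_h <- branch_length(tree, human_branch)
  if (!isTRUE(t_h > 0)) abort("Human stem branch length must be positive.")
  if (!isTRUE(t_l > 0)) abort("Lineage stem branch length must be positive.")
  rate * t_l / t_h
}

#' Binomial significance with Benjamini-Hochberg adjustment
#'
#' The raw p-value of a window is `P(X >= k)` for
#' `X ~ Binomial(window_length, rate)` (exact tail summation); adjusted
#' p-values are Benjamini-Hochberg step-up over all evaluated windows.
#' Event counts above the trial number are clipped with a warning.
#'
#' @param windows Window tibble from [windowed_event_counts()].
#' @param rate Expected per-base event rate in `(0, 1)`.
#' @param config A [screen_config()].
#' @return `windows` with `raw_p` and `adj_p`; the BH family size `m` is
#'   attached as an attribute.
#' @export
window_significance <- function(windows, rate, config = screen_config()) {
  if (!(rate > 0 && rate < 1)) abort("`rate` must be in (0, 1).")
  L <- config$window_length
  k <- windows$k
  if (any(k > L)) {
    warn("Event counts above the trial number; clipped to the window length.")
    k <- pmin(k, L)
  }
  raw_p <- pbinom(k - 1L, size = L, prob = rate, lower.tail = FALSE)
  windows$raw_p <- raw_p
  windows$adj_p <- p.adjust(raw_p, method = "BH")
  attr(windows, "m") <- length(raw_p)
  windows
}

#' Merge significant windows into diverged-region calls
#'
#' Windows with `adj_p < alpha_adj` are retained and overlapping or
#' book-ended windows merged; each call records its peak event count and
#' minimum adjusted p.
#'
#' @param windows Output of [window_significance()].
#' @param config A [screen_config()].
#' @return Tibble of calls: chrom, start, end, peak_k, min_adj_p, n_windows.
#' @export
call_aqers <- function(windows, config = screen_config()) {
  sig <- windows[windows$adj_p < config$alpha_adj, , drop = FALSE]
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  peak_k = integer(), min_adj_p = numeric(), n_windows = integer())
  if (nrow(sig) == 0L) return(empty)
  out <- lapply(split(sig, sig$chrom), function(s) {
    ir <- IRanges::IRanges(start = s$start + 1L, end = s$end)
    red <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hit)
    tibble(
      chrom = s$chrom[1],
      start = as.integer(IRanges::start(red)) - 1L,
      end = as.integer(IRanges::end(red)),
      peak_k = as.integer(tapply(s$k, grp, max)),
      min_adj_p = as.numeric(tapply(s$adj_p, grp, min)),
      n_windows = as.integer(tabulate(grp, nbins = length(red)))
    )
  })
  arrange(bind_rows(out), .data$chrom, .data$start)
}

#' Filter diverged-region calls
#'
#' Threshold mode keeps calls whose peak event count reaches `min_k`;
#' exclusion mode removes calls overlapping at least one base of an
#' interval set (e.g. satellites, segmental duplications, simple repeats).
#'
#' @param calls Call tibble from [call_aqers()].
#' @param min_k Optional minimum peak event count.
#' @param exclude Optional interval tibble to subtract hits against.
#' @return Filtered calls.
#' @export
filter_calls <- function(calls, min_k = NULL, exclude = NULL) {
  out <- calls
  if (!is.null(min_k)) out <- out[out$peak_k >= min_k, , drop = FALSE]
  if (!is.null(exclude) && nrow(out) > 0L) {
    check_intervals(exclude, "exclude")
    hits <- count_overlaps(out, exclude, per_element = TRUE)
    out <- out[hits == 0L, , drop = FALSE]
  }
  out
}

#' Run the full divergence screen between two nodes of an alignment
#'
#' Calls per-column events between two (typically reconstructed) rows,
#' counts them in sliding windows on reference coordinates, calibrates the
#' conservative expected rate from wide windows, assigns binomial/BH
#' significance, and merges significant windows into calls.
#'
#' @param aln A [prob_alignment] containing both node rows (see
#'   [reconstruct_ancestors()]).
#' @param node_a,node_b Row names of the two nodes to compare.
#' @param config A [screen_config()].
#' @param tree,lineage_branch,human_branch Optional: scale the calibrated
#'   rate by the lineage/human stem branch-length ratio.
#' @param chrom Chromosome name for outputs.
#' @return An `aqer_screen` object: `windows`, `calls`, `rate`, `config`.
#'   [tidy()] returns the calls, [glance()] the scan summary.
#' @export
aqer_screen <- function(aln, node_a, node_b, config = screen_config(),
                        tree = NULL, lineage_branch = NULL,
                        human_branch = "HUMANanc", chrom = "ref") {
  ta <- node_track(aln, node_a)
  tb <- node_track(aln, node_b)
  ev <- call_site_events(ta, tb, config)
  ref_ev <- events_to_ref(ev, aln$ref_coord_map, ta, tb)
  screen_from_ref_events(ref_ev, config, tree, lineage_branch, human_branch, chrom)
}

# Shared back half of the screen, also used by the streaming simulator.
screen_from_ref_events <- function(ref_ev, config, tree = NULL,
                                   lineage_branch = NULL,
                                   human_branch = "HUMANanc", chrom = "ref") {
  calib_w <- min(config$calibration_window, ref_ev$n_ref)
  calib <- windowed_event_counts(ref_ev, config, width = calib_w, step = calib_w,
                                 chrom = chrom)
  rate <- calibrate_expected_rate(calib, config)
  if (!is.null(lineage_branch)) {
    if (is.null(tree)) abort("Provide `tree` to scale for a lineage.")
    rate <- scale_rate_for_lineage(rate, tree, lineage_branch, human_branch)
  }
  rate <- rate * config$lineage_scale
  windows <- windowed_event_counts(ref_ev, config, chrom = chrom)
  windows <- window_significance(windows, rate, config)
  calls <- call_aqers(windows, config)
  structure(
    list(windows = windows, calls = calls, rate = rate, config = config,
         m = attr(windows, "m")),
    class = "aqer_screen"
  )
}

#' @export
print.aqer_screen <- function(x, ...) {
  cat(sprintf(
    "<aqer_screen> %d windows scanned (rate %.3g), %d call(s)\n",
    nrow(x$windows), x$rate, nrow(x$calls)
  ))
  invisible(x)
}

#' @rdname aqer_screen
#' @param x An `aqer_screen`.
#' @param ... Unused.
#' @method tidy aqer_screen
#' @export
tidy.aqer_screen <- function(x, ...) x$calls

#' @rdname aqer_screen
#' @method glance aqer_screen
#' @export
glance.aqer_screen <- function(x, ...) {
  tibble(n_windows = nrow(x$windows), rate = x$rate, n_calls = nrow(x$calls),
         alpha_adj = x$config$alpha_adj,
         max_adj_p_called = if (nrow(x$calls)) max(x$calls$min_adj_p) else NA_real_)
}

#' @rdname aqer_screen
#' @param object An `aqer_screen`.
#' @method autoplot aqer_screen
#' @export
autoplot.aqer_screen <- function(object, ...) {
  w <- object$windows
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$start, y = .data$k)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::labs(x = "reference position (bp)", y = "events per window",
                  title = "Divergence events along the reference") +
    ggplot2::theme_minimal()
  if (nrow(object$calls)) {
    p <- p + ggplot2::geom_rect(
      data = object$calls,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.2
    )
  }
  p
}

#' Joint polymorphism/divergence window scan with confidence filters
#'
#' Counts divergent substitution columns (gap events excluded) and
#' overlapping polymorphic sites in sliding windows, keeping only columns
#' where the ancestor's posterior is confident (max `>= conf`) and only
#' windows whose confident fraction of callable bases exceeds
#' `min_conf_frac`.
#'
#' @param aln A [prob_alignment] with both node rows.
#' @param node_anc,node_b Ancestor row (whose confidence is assessed) and
#'   comparison row.
#' @param variants Variant tibble with 0-based `pos`, or `NULL`.
#' @param width Window width (e.g. 500 or 50,000).
#' @param conf Posterior cutoff for a confident ancestor base.
#' @param min_conf_frac Minimum confident fraction for a window to be kept.
#' @param config A [screen_config()] (supplies the cosine threshold).
#' @return Tibble of retained windows with substitution, polymorphism and
#'   confident-base counts.
#' @export
poly_div_windows <- function(aln, node_anc, node_b, variants = NULL,
                             width = 500L, conf = 0.8, min_conf_frac = 0.9,
                             config = screen_config()) {
  ta <- node_track(aln, node_anc)
  tb <- node_track(aln, node_b)
  ev <- call_site_events(ta, tb, config)
  cols <- aln$ref_coord_map
  n_ref <- length(cols)
  conf_ok <- ta$present[cols] &
    apply(ta$probs[cols, , drop = FALSE], 1, max) >= conf
  conf_ok[is.na(conf_ok)] <- FALSE
  callable <- ta$present[cols] & tb$present[cols]
  sub <- as.integer(ev$label[cols] == "substitution" & conf_ok)
  poly <- integer(n_ref)
  if (!is.null(variants) && nrow(variants)) {
    poly <- tabulate(variants$pos + 1L, nbins = n_ref)
  }
  starts <- seq.int(0L, max(0L, n_ref - width), by = width)
  conf_callable <- as.integer(conf_ok & callable)
  out <- tibble(
    start = starts, end = starts + as.integer(width),
    substitutions = as.integer(window_sums(sub, width, starts)),
    polymorphisms = as.integer(window_sums(poly, width, starts)),
    n_callable = as.integer(window_sums(as.integer(callable), width, starts)),
    confident = as.integer(window_sums(conf_callable, width, starts))
  )
  out$callable <- out$n_callable
  out$n_callable <- NULL
  out$conf_frac <- ifelse(out$callable > 0, out$confident / out$callable, 0)
  out[out$conf_frac > min_conf_frac, , drop = FALSE]
}
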