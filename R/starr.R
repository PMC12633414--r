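# Single-cell STARR-seq enhancer activity: UMI deduplication, input and
# negative-control normalization, per-cell-type scores, a gamma null for
# right-tailed p-values, and pseudoreplicate binning.

#' Deduplicate UMIs into per-cell construct counts
#'
#' Identical (cell, umi, construct) triples collapse to a single molecule.
#'
#' @param records Tibble with cell, umi, construct columns.
#' @return Tibble of construct, cell, count (unique UMIs).
#' @export
dedupe_umis <- function(records) {
  need <- c("cell", "umi", "construct")
  if (!all(need %in% names(records))) abort("`records` needs cell/umi/construct columns.")
  records |>
    distinct(.data$cell, .data$umi, .data$construct) |>
    count(.data$construct, .data$cell, name = "count") |>
    arrange(.data$construct, .data$cell)
}

#' Enhancer activity scores
#'
#' Within each scope (pseudobulk, or one cell type when labels are given),
#' each construct's output UMI total is divided by its input-library count
#' and then by the mean such ratio over the negative-control constructs, so
#' negative controls average to a score of 1 by construction.  When any
#' negative control has zero output in a scope, add-one smoothing is
#' applied to the negative-control outputs of that scope (with a warning).
#'
#' @param counts Tibble of construct, cell, count (from [dedupe_umis()] or
#'   a count matrix pivot).
#' @param input Tibble of construct, input_count (> 0).
#' @param nc_ids Negative-control construct ids.
#' @param cell_types Optional tibble of cell, cell_type; when given, scores
#'   are computed per cell type (pseudobulk rows are not included).
#' @return Tibble: scope, construct, output, input_count, score, is_nc.
#' @export
activity_scores <- function(counts, input, nc_ids, cell_types = NULL) {
  if (any(input$input_count <= 0)) abort("Input counts must be positive for scored constructs.")
  if (!all(nc_ids %in% input$construct)) abort("All negative controls need input counts.")
  scoped <- if (is.null(cell_types)) {
    mutate(counts, scope = "pseudobulk")
  } else {
    inner_join(counts, cell_types, by = "cell") |>
      rename(scope = "cell_type")
  }
  out <- scoped |>
    group_by(.data$scope, .data$construct) |>
    summarise(output = sum(.data$count), .groups = "drop") |>
    # constructs with no output in a scope still get a (zero) score
    tidyr::complete(.data$scope, construct = input$construct,
                    fill = list(output = 0L)) |>
    inner_join(input, by = "construct") |>
    mutate(is_nc = .data$construct %in% nc_ids)
  out <- out |>
    group_by(.data$scope) |>
    group_modify(function(d, key) {
      nc <- d[d$is_nc, ]
      if (all(nc$output == 0)) {
        abort(sprintf("Scope '%s': all negative controls have zero output.", key$scope))
      }
      if (any(nc$output == 0)) {
        warn(sprintf("Scope '%s': zero-output negative control; add-one smoothing applied.",
                     key$scope))
        d$output[d$is_nc] <- d$output[d$is_nc] + 1L
      }
      ratio <- d$output / d$input_count
      nc_mean <- mean(ratio[d$is_nc])
      d$score <- ratio / nc_mean
      d
    }) |>
    ungroup()
  arrange(out, .data$scope, .data$construct)
}

# Method-of-moments gamma parameters.
gamma_moments <- function(x) {
  m <- mean(x); v <- var(x)
  if (!is.finite(v) || v <= 0) abort("Cannot fit a gamma to degenerate scores.")
  list(shape = m^2 / v, rate = m / v)
}

#' Right-tailed p-values against a gamma null of negative controls
#'
#' Fits a gamma distribution to the negative-control activity scores of
#' each scope (maximum likelihood via [MASS::fitdistr()]; method of
#' moments as fallback, with a warning) and reports the upper-tail
#' probability of each construct's score, plus a BH-adjusted column.
#'
#' @param scores Tibble from [activity_scores()].
#' @param min_nc Minimum number of positive negative-control scores.
#' @return `scores` with p_right and adj_p columns; per-scope gamma
#'   parameters in the `"gamma_fits"` attribute.
#' @export
gamma_null_test <- function(scores, min_nc = 3L) {
  fits <- list()
  out <- scores |>
    group_by(.data$scope) |>
    group_modify(function(d, key) {
      nc <- d$score[d$is_nc & d$score > 0]
      if (length(nc) < min_nc) {
        abort(sprintf("Scope '%s': need at least %d positive negative-control scores.",
                      key$scope, min_nc))
      }
      fit <- tryCatch(
        {
          f <- suppressWarnings(MASS::fitdistr(nc, "gamma"))
          list(shape = unname(f$estimate["shape"]), rate = unname(f$estimate["rate"]))
        },
        error = function(e) {
          warn(sprintf("Scope '%s': gamma MLE failed (%s); using method of moments.",
                       key$scope, conditionMessage(e)))
          gamma_moments(nc)
        }
      )
      fits[[key$scope]] <<- fit
      d$p_right <- pgamma(d$score, shape = fit$shape, rate = fit$rate,
                          lower.tail = FALSE)
      d
    }) |>
    ungroup() |>
    mutate(adj_p = p.adjust(.data$p_right, method = "BH"))
  attr(out, "gamma_fits") <- fits
  out
}

#' Assign cells to pseudoreplicate bins
#'
#' Randomly assorts cells into `k` bins (seeded), then validates that every
#' bin holds more than one read of every negative-control construct;
#' offending bins are reported in the error so the caller can lower `k`.
#'
#' @param cells Character vector of cell ids.
#' @param counts Count tibble (construct, cell, count) used for validation.
#' @param nc_ids Negative-control construct ids.
#' @param k Number of bins (>= 2).
#' @param seed Integer seed.
#' @return Tibble of cell, bin.
#' @export
pseudoreplicate_bins <- function(cells, counts, nc_ids, k = 5L, seed = 1L) {
  if (k < 2L) abort("`k` must be at least 2 bins.")
  bins <- with_seed(seed, sample(rep_len(seq_len(k), length(cells))))
  assignment <- tibble(cell = cells, bin = bins)
  chk <- counts |>
    filter(.data$construct %in% nc_ids) |>
    inner_join(assignment, by = "cell") |>
    group_by(.data$bin, .data$construct) |>
    summarise(reads = sum(.data$count), .groups = "drop") |>
    tidyr::complete(bin = seq_len(k), construct = nc_ids, fill = list(reads = 0L))
  bad <- unique(chk$bin[chk$reads <= 1L])
  if (length(bad)) {
    abort(sprintf("Bin(s) %s lack > 1 read of every negative control; lower `k`.",
                  paste(sort(bad), collapse = ", ")))
  }
  assignment
}

#' Plot enhancer activity scores
#'
#' @param scores Output of [activity_scores()] (optionally after
#'   [gamma_null_test()]).
#' @return A ggplot object: scores by construct, faceted by scope, with
#'   negative controls highlighted.
#' @export
plot_activity <- function(scores) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$construct, y = .data$score,
                               fill = .data$is_nc)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scope) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue", `TRUE` = "grey60"),
                               name = "negative control") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "activity score (input- and NC-normalised)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
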