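# Event calling, window counting, calibration, significance, and call
# merging/filtering.

track_from_bases <- function(s) {
  aln <- prob_alignment(list(x = strsplit(s, "")[[1]]))
  node_track(aln, "x")
}

test_that("cosine distance labels substitutions at the 0.8 threshold", {
  cfg <- screen_config()
  onehot <- function(i) { v <- rep(0, 4); v[i] <- 1; v }
  u <- rbind(onehot(1), onehot(1), c(0.5, 0.5, 0, 0))
  v <- rbind(onehot(1), onehot(2), onehot(1))
  ta <- list(present = rep(TRUE, 3), probs = u)
  tb <- list(present = rep(TRUE, 3), probs = v)
  ev <- call_site_events(ta, tb, cfg)
  expect_equal(ev$distance, c(0, 1, 1 - 1 / sqrt(2)))
  expect_equal(as.character(ev$label), c("none", "substitution", "none"))
  # substitution count is monotone non-increasing in the threshold
  withr::with_seed(2, {
    pa <- matrix(rgamma(200 * 4, 1), 200)
    pa <- pa / rowSums(pa)
    pb <- matrix(rgamma(200 * 4, 1), 200)
    pb <- pb / rowSums(pb)
    ta <- list(present = rep(TRUE, 200), probs = pa)
    tb <- list(present = rep(TRUE, 200), probs = pb)
    taus <- seq(0.1, 1, by = 0.1)
    counts <- vapply(taus, function(tau) {
      sum(call_site_events(ta, tb, screen_config(cosine_threshold = tau))$label ==
            "substitution")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    d <- call_site_events(ta, tb, cfg)$distance
    expect_equal(sum(d >= 0.8), counts[8])
  })
  # zero-magnitude vectors violate the contract
  bad <- list(present = TRUE, probs = matrix(0, 1, 4))
  expect_error(call_site_events(bad, bad, cfg), "Zero-magnitude")
})

test_that("each maximal one-sided run is one gap event anchored at its start", {
  pa <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  pb <- c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  probs <- matrix(rep(c(1, 0, 0, 0), each = 10), 10)
  ev <- call_site_events(list(present = pa, probs = probs),
                         list(present = pb, probs = probs), screen_config())
  expect_equal(ev$gap_anchors, c(2L, 7L, 10L))
  expect_equal(sum(ev$label == "in_gap_event"), 6L)
})

test_that("window counts match a brute-force per-column scan", {
  withr::with_seed(14, {
    n <- 3000L
    pa <- runif(n) > 0.05
    pb <- runif(n) > 0.05
    base_a <- sample.int(4L, n, replace = TRUE)
    base_b <- ifelse(runif(n) < 0.04, 1L + base_a %% 4L, base_a)
    mk <- function(code, pres) {
      probs <- matrix(0, n, 4)
      probs[cbind(seq_len(n), code)] <- 1
      list(present = pres, probs = probs)
    }
    ta <- mk(base_a, pa)
    tb <- mk(base_b, pb)
    cfg <- screen_config(window_length = 100L, window_step = 50L)
    ev <- call_site_events(ta, tb, cfg)
    ref_map <- seq_len(n)   # every column is a reference base
    ref_ev <- aqerscan:::events_to_ref(ev, ref_map, ta, tb)
    win <- windowed_event_counts(ref_ev, cfg)
    # oracle: direct scan over columns per window
    lab <- as.character(ev$label)
    anchors <- ev$gap_anchors
    for (i in seq_len(nrow(win))) {
      span <- (win$start[i] + 1L):win$end[i]
      expect_equal(win$k_s[i], sum(lab[span] == "substitution"))
      expect_equal(win$k_g[i], sum(anchors %in% span))
      expect_equal(win$k[i], win$k_s[i] + win$k_g[i])
      expect_equal(win$callable[i], sum(pa[span] & pb[span]))
    }
  })
})

test_that("a long gap run inside one window contributes a single event", {
  n <- 1200L
  pa <- rep(TRUE, n)
  pb <- rep(TRUE, n)
  pb[301:340] <- FALSE          # one 40-base deletion
  probs <- matrix(rep(c(1, 0, 0, 0), each = n), n)
  ta <- list(present = pa, probs = probs)
  tb <- list(present = pb, probs = probs)
  cfg <- screen_config(window_length = 500L, window_step = 500L)
  ev <- call_site_events(ta, tb, cfg)
  ref_ev <- aqerscan:::events_to_ref(ev, seq_len(n), ta, tb)
  win <- windowed_event_counts(ref_ev, cfg)
  expect_equal(win$k_g, c(1L, 0L))
})

test_that("calibration takes the maximum qualifying window rate", {
  win <- tibble::tibble(chrom = "c", start = c(0, 10, 20) * 1000L,
                        end = c(10, 20, 30) * 1000L,
                        k = c(10L, 20L, 15L),
                        callable = c(10000L, 10000L, 10000L))
  expect_equal(calibrate_expected_rate(win), 0.002)
  expect_equal(calibrate_expected_rate(win[1, ]), 0.001)
  # windows failing the callable fraction are ignored
  win$callable <- c(10000L, 2000L, 10000L)
  expect_equal(calibrate_expected_rate(win), 0.0015)
  win$callable <- rep(100L, 3)
  expect_error(calibrate_expected_rate(win), "callable fraction")
})

test_that("lineage scaling multiplies by the stem branch ratio", {
  tree <- great_ape_tree()
  expect_equal(scale_rate_for_lineage(0.001, tree, "HUMANanc"), 0.001)
  gor <- scale_rate_for_lineage(0.001, tree, "gorillaT2Tanc")
  expect_equal(gor, 0.001 * 0.00856474 / 0.00606109)
  expect_equal(scale_rate_for_lineage(0.002, tree, "gorillaT2Tanc"), 2 * gor)
})

test_that("binomial tails and BH match independent oracles", {
  cfg <- screen_config(window_length = 500L)
  # tiny enumerable case: k=2, L=3, p=0.5 -> P(X>=2) = 4/8
  w <- tibble::tibble(chrom = "c", start = 0L, end = 3L, k_s = 2L, k_g = 0L,
                      k = 2L, callable = 3L)
  cfg3 <- screen_config(window_length = 25L)
  raw <- pbinom(1, 3, 0.5, lower.tail = FALSE)
  expect_equal(raw, 0.5)
  withr::with_seed(6, {
    for (r in 1:200) {
      L <- sample(c(50L, 500L, 2000L), 1)
      p <- runif(1, 1e-5, 0.05)
      k <- sample(0:12, 1)
      got <- pbinom(k - 1L, L, p, lower.tail = FALSE)
      expect_lt(abs(got - binom_tail_oracle(k, L, p)), 1e-12)
    }
    # BH vs sort-based oracle on random p-lists
    for (r in 1:200) {
      p <- runif(sample(2:40, 1))
      expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    }
  })
  # worked step-up example
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("window significance clips k, computes exact tails, and k=0 gives p=1", {
  cfg <- screen_config(window_length = 500L)
  w <- tibble::tibble(chrom = "c", start = c(0L, 500L), end = c(500L, 1000L),
                      k_s = c(0L, 600L), k_g = 0L, k = c(0L, 600L),
                      callable = 500L)
  expect_warning(out <- window_significance(w, 0.005, cfg), "clipped")
  expect_equal(out$raw_p[1], 1)
  expect_equal(attr(out, "m"), 2L)
  expect_true(all(out$adj_p >= out$raw_p - 1e-15))
})

test_that("significant windows merge into calls and filters behave", {
  cfg <- screen_config()
  w <- tibble::tibble(
    chrom = "c", start = c(100L, 400L, 2000L), end = c(600L, 900L, 2500L),
    k_s = c(30L, 35L, 40L), k_g = 0L, k = c(30L, 35L, 40L), callable = 500L,
    raw_p = c(1e-12, 1e-14, 1e-16), adj_p = c(1e-9, 1e-11, 1e-13)
  )
  calls <- call_aqers(w, cfg)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$start[1], 100L)
  expect_equal(calls$end[1], 900L)
  expect_equal(calls$peak_k, c(35L, 40L))
  # no significant window -> empty call set
  w0 <- w; w0$adj_p <- 0.5
  expect_equal(nrow(call_aqers(w0, cfg)), 0L)
  # threshold filter
  expect_equal(nrow(filter_calls(calls, min_k = 39)), 1L)
  expect_equal(nrow(filter_calls(calls, min_k = 35)), 2L)
  # exclusion filter
  excl <- tibble::tibble(chrom = "c", start = 0L, end = 10000L)
  expect_equal(nrow(filter_calls(calls, exclude = excl)), 0L)
  excl2 <- tibble::tibble(chrom = "c", start = 950L, end = 1000L)
  expect_equal(nrow(filter_calls(calls, exclude = excl2)), 2L)
})

test_that("the end-to-end screen finds a planted window and honours coordinates", {
  tree <- great_ape_tree()
  pl <- tibble::tibble(start = 20000L, end = 20500L, multiplier = 14)
  res <- simulate_divergence_screen(tree, 50000, planted = pl, seed = 5,
                                    config = screen_config(calibration_window = 25000))
  calls <- res$screen$calls
  expect_equal(nrow(calls), 1L)
  expect_lt(calls$start[1], pl$end[1])
  expect_gt(calls$end[1], pl$start[1])
  expect_true(all(res$screen$windows$adj_p[res$screen$windows$adj_p <
                                             res$screen$config$alpha_adj] < 3e-7))
})

test_that("poly/div distribution scan honours the confidence filters", {
  tree <- great_ape_tree()
  sim <- simulate_alignment(tree, 4000, seed = 23)
  aln <- reconstruct_ancestors(sim$alignment, tree, c("hcaT2T", "HUMANanc"))
  win <- poly_div_windows(aln, "hcaT2T", "HUMANanc", width = 500L,
                          conf = 0.8, min_conf_frac = 0.9)
  expect_true(all(win$conf_frac > 0.9))
  # confident columns only: recount substitutions with the filter by hand
  ta <- node_track(aln, "hcaT2T")
  tb <- node_track(aln, "HUMANanc")
  ev <- call_site_events(ta, tb)
  cols <- aln$ref_coord_map
  confident <- ta$present[cols] &
    apply(ta$probs[cols, , drop = FALSE], 1, max) >= 0.8
  confident[is.na(confident)] <- FALSE
  lab <- as.character(ev$label[cols])
  for (i in seq_len(nrow(win))) {
    span <- (win$start[i] + 1L):win$end[i]
    expect_equal(win$substitutions[i],
                 sum(lab[span] == "substitution" & confident[span]))
  }
  # a lenient confidence cutoff never yields fewer substitutions
  win0 <- poly_div_windows(aln, "hcaT2T", "HUMANanc", width = 500L,
                           conf = 0, min_conf_frac = 0)
  shared <- intersect(win$start, win0$start)
  expect_true(all(win$substitutions[match(shared, win$start)] <=
                    win0$substitutions[match(shared, win0$start)]))
})
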