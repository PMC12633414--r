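# Interval algebra, the placement-null enrichment framework, RAND regions,
# GC content, and posterior filtering.

tb <- function(...) tibble::tibble(...)

test_that("merge and subtract follow half-open semantics", {
  x <- tb(chrom = "c", start = c(10L, 20L), end = c(20L, 30L))
  m <- merge_intervals(x)
  expect_equal(m, tb(chrom = "c", start = 10L, end = 30L))
  # merge is idempotent
  expect_equal(merge_intervals(m), m)
  a <- tb(chrom = "c", start = 0L, end = 100L)
  b <- tb(chrom = "c", start = 40L, end = 60L)
  s <- subtract_intervals(a, b)
  expect_equal(s, tb(chrom = c("c", "c"), start = c(0L, 60L), end = c(40L, 100L)))
  # subtract(a, empty) = merge(a)
  empty <- tb(chrom = character(), start = integer(), end = integer())
  expect_equal(subtract_intervals(x, empty), m)
  # subtraction result never intersects b
  withr::with_seed(4, {
    for (r in 1:10) {
      aa <- tb(chrom = "c", start = sample(0:5000, 15))
      aa$end <- aa$start + sample(1:400, 15, replace = TRUE)
      bb <- tb(chrom = "c", start = sample(0:5000, 10))
      bb$end <- bb$start + sample(1:400, 10, replace = TRUE)
      expect_equal(count_overlaps(subtract_intervals(aa, bb), bb), 0L)
    }
  })
})

test_that("overlap counting matches a quadratic all-pairs oracle", {
  expect_equal(count_overlaps(tb(chrom = "c", start = 10L, end = 20L),
                              tb(chrom = "c", start = 20L, end = 30L)), 0L)
  expect_equal(count_overlaps(tb(chrom = "c", start = 10L, end = 20L),
                              tb(chrom = "c", start = 12L, end = 15L)), 1L)
  withr::with_seed(9, {
    for (r in 1:20) {
      a <- tb(chrom = sample(c("c1", "c2"), 30, replace = TRUE),
              start = sample(0:2000, 30))
      a$end <- a$start + sample(1:100, 30, replace = TRUE)
      b <- tb(chrom = sample(c("c1", "c2"), 20, replace = TRUE),
              start = sample(0:2000, 20))
      b$end <- b$start + sample(1:100, 20, replace = TRUE)
      oracle <- sum(vapply(seq_len(nrow(a)), function(i) {
        any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i])
      }, logical(1)))
      expect_equal(count_overlaps(a, b), oracle)
    }
  })
})

test_that("saturated and empty annotations give the degenerate enrichments", {
  genome <- tb(chrom = "c", size = 10000L)
  a <- tb(chrom = "c", start = seq(0L, 9000L, by = 1000L), end = seq(0L, 9000L, by = 1000L) + 100L)
  b_all <- tb(chrom = "c", start = 0L, end = 10000L)
  res <- overlap_enrichment(a, b_all, genome)
  expect_equal(res$expected, nrow(a))
  expect_equal(res$observed, nrow(a))
  expect_equal(res$ratio, 1)
  expect_equal(res$p_two, 1)
  b_none <- tb(chrom = character(), start = integer(), end = integer())
  res0 <- overlap_enrichment(a, b_none, genome)
  expect_equal(res0$expected, 0)
  expect_equal(res0$p_two, 1)
  expect_equal(res0$direction, "undefined")
})

test_that("enrichment p-values sit inside a Monte-Carlo permutation band", {
  # 10-kb toy genome, 20 elements, 10% annotation coverage
  genome <- tb(chrom = "c", size = 10000L)
  b <- tb(chrom = "c", start = c(1000L, 5000L), end = c(1500L, 5500L))
  withr::with_seed(3, {
    w <- 50L
    a <- simulate_rand_regions(tb(chrom = "c", start = 0L, end = 10000L),
                               n = 20, mean_len = w, seed = 3)
    res <- overlap_enrichment(a, b, genome)
    # permutation oracle: 20,000 random placements of 20 elements
    n_rep <- 20000L
    obs <- res$observed
    starts_max <- 10000L - w
    counts <- vapply(seq_len(n_rep), function(r) {
      s <- sample.int(starts_max + 1L, 20L, replace = TRUE) - 1L
      sum(s < 1500L & s + w > 1000L | s < 5500L & s + w > 5000L)
    }, numeric(1))
    tail_ge <- mean(counts >= obs)
    tail_le <- mean(counts <= obs)
    p_mc <- min(1, 2 * min(tail_ge, tail_le))
    band <- 2 * 1.96 * sqrt(p_mc * (1 - p_mc) / n_rep) + 0.01
    expect_lt(abs(res$p_two - p_mc), band + 0.05 * p_mc)
    # expected count agrees with the empirical mean of the oracle
    expect_lt(abs(res$expected - mean(counts)), 0.1)
  })
})

test_that("null enrichment p-values are super-uniform at the 5% level", {
  genome <- tb(chrom = "c", size = 50000L)
  bg <- tb(chrom = "c", start = 0L, end = 50000L)
  b <- tb(chrom = "c", start = seq(0L, 45000L, by = 5000L))
  b$end <- b$start + 500L
  ps <- vapply(1:300, function(s) {
    a <- simulate_rand_regions(bg, n = 15, mean_len = 80, seed = s)
    overlap_enrichment(a, b, genome)$p_two
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.05 + 0.03)
  # self-enrichment ratio is at least 1
  a1 <- simulate_rand_regions(bg, n = 15, mean_len = 80, seed = 1)
  expect_gte(overlap_enrichment(a1, a1, genome)$ratio, 1)
})

test_that("bonferroni and BH adjustments apply across a results table", {
  res <- tb(p_two = c(0.01, 0.02, 0.04))
  expect_equal(adjust_enrichments(res)$adj_p, pmin(1, res$p_two * 3))
  expect_equal(adjust_enrichments(res, "BH")$adj_p, p.adjust(res$p_two, "BH"))
})

test_that("RAND regions respect count, length, background, and seeds", {
  bg <- tb(chrom = c("c1", "c2"), start = c(100L, 0L), end = c(5000L, 3000L))
  for (seed in c(10L, 40L, 70L)) {
    r <- simulate_rand_regions(bg, n = 25, mean_len = 36.6, seed = seed)
    expect_equal(nrow(r), 25L)
    expect_true(all(r$end - r$start == 37L))
    # inside the background, never crossing block boundaries
    expect_equal(sum(count_overlaps(r, bg, per_element = TRUE)), 25L)
    expect_equal(nrow(subtract_intervals(r, bg)), 0L)
    # non-self-overlapping
    m <- merge_intervals(r)
    expect_equal(sum(m$end - m$start), 25L * 37L)
    # reproducible
    expect_identical(r, simulate_rand_regions(bg, n = 25, mean_len = 36.6,
                                              seed = seed))
  }
  r10 <- simulate_rand_regions(bg, 25, 36.6, 10L)
  r40 <- simulate_rand_regions(bg, 25, 36.6, 40L)
  expect_false(identical(r10, r40))
  expect_error(simulate_rand_regions(bg, n = 10000, mean_len = 500, seed = 1),
               "capacity")
})

test_that("GC fractions, classes, and the background chi-squared test", {
  out <- gc_content(c("GGCC", "ATGC", "AATT"))
  expect_equal(out$gc, c(1, 0.5, 0))
  expect_equal(out$class, c("rich", "mid", "poor"))
  # Ns are excluded from the denominator
  expect_equal(gc_content("GGNN")$gc, 1)
  expect_warning(gc_content("NNNN"), "no A/C/G/T")
  ht <- gc_enrichment_test(c("rich", "rich", "mid", "poor"),
                           rep(c("rich", "mid", "poor"), c(5, 90, 5)), "rich")
  manual <- suppressWarnings(chisq.test(rbind(c(2, 2), c(5, 95)), correct = FALSE))
  expect_equal(ht$statistic, unname(manual$statistic))
  expect_equal(ht$p.value, unname(manual$p.value))
})

test_that("posterior filtering is inclusive at the cutoff and validates input", {
  trk <- tb(chrom = "c", start = c(0L, 10L, 20L), end = c(10L, 20L, 30L),
            value = c(0.59, 0.6, 0.61))
  expect_equal(nrow(posterior_filter(trk, 0.6)), 2L)
  expect_equal(nrow(posterior_filter(trk, 0)), 3L)
  expect_equal(nrow(posterior_filter(trk, 1)), 0L)
  trk$value[1] <- 1.2
  expect_error(posterior_filter(trk, 0.5), "\\[0, 1\\]")
})
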