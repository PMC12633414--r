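# Divergent-site extraction, fixed/polymorphic partitions, proximity
# blocking, spectra, reversion classification, and signal comparisons.

test_that("divergent sites are substitutions only, matching a column scan", {
  tree <- great_ape_tree()
  sim <- simulate_alignment(tree, 3000, seed = 41)
  aln <- reconstruct_ancestors(sim$alignment, tree, c("hcaT2T", "HUMANanc"))
  sites <- extract_divergent_sites(aln, "hcaT2T", "HUMANanc")
  ev <- call_site_events(node_track(aln, "hcaT2T"), node_track(aln, "HUMANanc"))
  sub_cols <- which(ev$label == "substitution")
  on_ref <- sub_cols %in% aln$ref_coord_map
  expect_equal(nrow(sites), sum(on_ref))
  expect_true(all(sites$end - sites$start == 1L))
  # identical tracks -> no divergent sites
  aln_same <- prob_alignment(list(a = rep("A", 10), b = rep("A", 10)))
  expect_equal(nrow(extract_divergent_sites(aln_same, "a", "b")), 0L)
})

test_that("fixed + polymorphic partition is exhaustive and labels correctly", {
  div <- tibble::tibble(chrom = "c", start = c(10L, 20L, 30L), end = c(11L, 21L, 31L))
  vars <- tibble::tibble(chrom = "c", pos = c(20L, 99L))
  out <- partition_fixed_polymorphic(div, vars)
  expect_equal(out$status, c("fixed", "polymorphic", "fixed"))
  expect_equal(sum(out$status == "fixed") + sum(out$status == "polymorphic"),
               nrow(div))
})

test_that("fixed/polymorphic chi-squared matches hand-computed tables", {
  s1 <- rep(c("fixed", "polymorphic"), c(10, 10))
  s2 <- rep(c("fixed", "polymorphic"), c(10, 10))
  t1 <- fixed_poly_test(s1, s2)
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p.value, 1)
  s3 <- rep(c("fixed", "polymorphic"), c(20, 10))
  s4 <- rep(c("fixed", "polymorphic"), c(10, 20))
  t2 <- fixed_poly_test(s3, s4)
  expect_equal(t2$statistic, 100 / 15)
  # all-polymorphic set has proportion 1
  s5 <- rep("polymorphic", 5)
  t3 <- fixed_poly_test(s5, s3)
  expect_equal(t3$set_poly_prop, 1)
  # zero expected cell -> error advising an exact test
  expect_error(fixed_poly_test(rep("fixed", 4), rep("fixed", 4)), "exact test")
  # densities
  t4 <- fixed_poly_test(s3, s4, set_bases = 300, ref_bases = 300)
  expect_equal(t4$set_div_per_base, 0.1)
  expect_equal(t4$set_poly_per_base, 10 / 300)
})

test_that("proximity blocking is maximal, spaced, and seed-reproducible", {
  v <- tibble::tibble(chrom = "c", pos = c(0L, 5000L, 12000L))
  out <- proximity_block(v, min_dist = 10000L, seed = 1)
  expect_true(identical(out$pos, c(0L, 12000L)) || identical(out$pos, 5000L))
  # single variant is retained
  expect_equal(nrow(proximity_block(v[1, ], seed = 1)), 1L)
  withr::with_seed(77, {
    for (r in 1:10) {
      n <- 200L
      vv <- tibble::tibble(
        chrom = sample(c("c1", "c2"), n, replace = TRUE),
        pos = sample.int(3e5, n)
      )
      for (seed in c(10L, 40L, 70L)) {
        kept <- proximity_block(vv, min_dist = 10000L, seed = seed)
        # pairwise spacing invariant
        for (ch in unique(kept$chrom)) {
          p <- sort(kept$pos[kept$chrom == ch])
          if (length(p) > 1L) expect_true(all(diff(p) >= 10000L))
        }
        # greedy maximality: every rejected variant is within min_dist of a kept one
        rej <- dplyr::anti_join(vv, kept, by = c("chrom", "pos"))
        if (nrow(rej)) {
          near <- vapply(seq_len(nrow(rej)), function(i) {
            any(kept$chrom == rej$chrom[i] &
                  abs(kept$pos - rej$pos[i]) < 10000L)
          }, logical(1))
          expect_true(all(near))
        }
        # determinism
        expect_identical(kept, proximity_block(vv, min_dist = 10000L, seed = seed))
      }
      # distinct seeds usually give distinct subsets; at minimum reproducible
      k10 <- proximity_block(vv, min_dist = 10000L, seed = 10L)
      k40 <- proximity_block(vv, min_dist = 10000L, seed = 40L)
      expect_true(nrow(k10) > 0 && nrow(k40) > 0)
    }
  })
})

test_that("spectra count classes correctly and fold onto MAF", {
  v <- tibble::tibble(daf = c(0.1, 0.1, 0.7), ac = c(1L, 1L, 7L), an = 10L)
  sp <- allele_frequency_spectrum(v, polarized = TRUE)
  expect_equal(sum(sp$count), 3L)
  expect_equal(sp$count[sp$i == 1], 2L)
  expect_equal(sp$count[sp$i == 7], 1L)
  # all singletons -> all mass in the lowest class
  v1 <- tibble::tibble(daf = rep(0.1, 5), ac = 1L, an = 10L)
  sp1 <- allele_frequency_spectrum(v1, polarized = TRUE)
  expect_equal(sp1$count[1], 5L)
  expect_equal(sum(sp1$count[-1]), 0L)
  # DAF 0.7 folds to MAF 0.3
  un <- allele_frequency_spectrum(v, polarized = FALSE)
  expect_equal(un$count[un$i == 3], 1L)
  expect_true(all(un$freq <= 0.5))
  # folding the polarized spectrum reproduces the unpolarized one
  expect_equal(fold_spectrum(sp, 10L)$count[fold_spectrum(sp, 10L)$i %in% un$i],
               un$count[un$i %in% fold_spectrum(sp, 10L)$i])
})

test_that("neutral simulated variants reproduce the 1/i spectrum", {
  v <- simulate_variants(5000, gamma = 0, n_alleles = 1002L, seed = 2)
  expect_true(all(v$an == 1002L))
  sp <- allele_frequency_spectrum(v, polarized = TRUE)
  # chi-squared GOF against expected proportions 1/i over binned classes
  bins <- cut(rep(sp$i, sp$count), breaks = c(0, 1, 2, 5, 10, 50, 200, 1001))
  expect_gt(sum(sp$count), 0)
  expected <- tapply(1 / sp$i, cut(sp$i, breaks = c(0, 1, 2, 5, 10, 50, 200, 1001)), sum)
  obs <- table(bins)
  gof <- chisq.test(as.numeric(obs), p = as.numeric(expected) / sum(expected))
  expect_gt(gof$p.value, 0.01)
})

test_that("high-DAF classification separates reversion from ancestral haplotypes", {
  # 3 sites x 20 haplotypes; focal site has DAF 0.95+ (19/20 derived)
  gt <- rbind(
    c(0L, rep(1L, 19L)),              # focal: haplotype 1 is ancestral
    c(0L, rep(1L, 19L)),              # nearby divergent site
    rep(1L, 20L)
  )
  v <- tibble::tibble(pos = c(5000L, 5500L, 6000L), daf = c(0.95 + 1e-9, 0.95, 1))
  attr(v, "gt") <- gt
  divergent <- c(TRUE, TRUE, TRUE)
  # carrier is ancestral at the nearby divergent site -> incomplete sweep
  expect_equal(classify_high_daf_site(1, v, divergent, context_w = 2000L),
               "ancestral_haplotype")
  # carrier derived at all other nearby divergent sites -> reversion
  gt2 <- gt; gt2[2, 1] <- 1L
  attr(v, "gt") <- gt2
  expect_equal(classify_high_daf_site(1, v, divergent, context_w = 2000L),
               "reversion_candidate")
  # below the DAF cutoff -> not applicable
  expect_equal(classify_high_daf_site(2, v, divergent), "not_applicable")
  # invariance to haplotype ordering
  perm <- sample(20)
  v3 <- v; attr(v3, "gt") <- gt2[, perm]
  expect_equal(classify_high_daf_site(1, v3, divergent, context_w = 2000L),
               "reversion_candidate")
  # inconsistent data: DAF < 1 but no ancestral carrier
  gt4 <- gt; gt4[1, ] <- 1L
  v4 <- v; attr(v4, "gt") <- gt4
  expect_error(classify_high_daf_site(1, v4, divergent), "inconsisten")
})

test_that("mean per-element signal and Welch tests behave", {
  sig <- tibble::tibble(chrom = "c", pos = 0:99,
                        value = c(rep(1, 50), rep(3, 50)))
  sets <- list(
    x = tibble::tibble(chrom = "c", start = 0L, end = 100L),
    y = tibble::tibble(chrom = "c", start = c(0L, 200L), end = c(50L, 300L)),
    ref = tibble::tibble(chrom = "c", start = c(0L, 50L), end = c(50L, 100L))
  )
  out <- mean_signal_per_element(sets, sig, reference = "ref")
  expect_equal(out$means$mean_signal[out$means$set == "x"], 2)
  # constant signal -> every covered mean equals the constant
  expect_equal(out$means$mean_signal[out$means$set == "y"], 1)
  expect_equal(out$tests$n_dropped[out$tests$set == "y"], 1L)
  expect_true(all(out$tests$adj_p >= out$tests$p.value, na.rm = TRUE))
  sig0 <- tibble::tibble(chrom = "zz", pos = 0:9, value = 1)
  expect_error(mean_signal_per_element(sets, sig0, "ref"), "overlaps")
})

test_that("null t-test p-values are roughly uniform across replicates", {
  withr::with_seed(123, {
    p <- replicate(400, {
      a <- rnorm(30); b <- rnorm(30)
      t.test(a, b)$p.value
    })
    expect_gt(ks.test(p, "punif")$p.value, 0.01)
  })
})
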