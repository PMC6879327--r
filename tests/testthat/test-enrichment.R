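test_that("Fisher p-values match the enumeration-derived worked values", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)), 2 / 252,
               tolerance = 1e-12)
  for (k in c(1, 3, 10)) {
    expect_equal(fisher_exact_2x2(matrix(k, 2, 2)), 1)
  }
  expect_warning(p <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(p, 1)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  withr::with_seed(19, {
    for (i in 1:200) {
      tab <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                   tolerance = 1e-10)
    }
  })
})

test_that("odds ratio is 1 exactly for proportional rows and inverts under row swap", {
  e <- quadchip:::odds_ratio_2x2
  expect_equal(e(10, 20, 5, 10), 1)
  expect_equal(e(3, 7, 6, 14), 1)
  r <- e(8, 3, 2, 9)
  expect_equal(e(2, 9, 8, 3), 1 / r)
  expect_gt(e(0, 5, 5, 0), 0) # continuity correction keeps it finite and positive
})

test_that("control regions are length-matched, deterministic, and avoid exclusions", {
  withr::with_seed(4, {
    g <- genome(c(chr1 = random_dna(6000), chr2 = random_dna(3000)))
  })
  peaks <- tibble::tibble(chrom = "chr1", start = c(1000, 4000), end = c(1300, 4200))
  ctrl <- sample_control_regions(peaks, g, n_per_peak = 100, seed = 7, genome = g)
  expect_equal(nrow(ctrl), 200L)
  expect_equal(unique(ctrl$end - ctrl$start), c(300, 200))
  expect_identical(ctrl,
                   sample_control_regions(peaks, g, n_per_peak = 100, seed = 7, genome = g))
  # no control overlaps an excluded (peak) interval
  for (j in seq_len(nrow(peaks))) {
    expect_false(any(ctrl$chrom == peaks$chrom[j] & ctrl$start < peaks$end[j] &
                       peaks$start[j] < ctrl$end))
  }
})

test_that("a peak of length L-1 on a length-L chromosome leaves only starts 0 and 1", {
  g <- genome(c(only = random_dna(50)))
  peaks <- tibble::tibble(chrom = "only", start = 0, end = 49)
  ctrl <- sample_control_regions(peaks, g, n_per_peak = 50, seed = 2,
                                 exclusions = peaks[0, ])
  expect_true(all(ctrl$start %in% c(0, 1)))
  # with the peak itself excluded no placement exists at all
  expect_error(sample_control_regions(peaks, g, n_per_peak = 5, seed = 2, max_draws = 50),
               "budget")
})

test_that("control sampling is length-weighted across chromosomes", {
  sz <- c(chr1 = 30000, chr2 = 10000)
  g <- withr::with_seed(12, genome(c(chr1 = random_dna(30000), chr2 = random_dna(10000))))
  peaks <- tibble::tibble(chrom = "chr1", start = 0, end = 50)
  ctrl <- sample_control_regions(peaks, sz, n_per_peak = 10000, seed = 99,
                                 exclusions = peaks[0, ])
  obs <- table(factor(ctrl$chrom, names(sz)))
  p <- stats::chisq.test(obs, p = sz / sum(sz))$p.value
  expect_gt(p, 0.01)
})

test_that("enrichment reports carry a valid table and direction", {
  g <- withr::with_seed(5, genome(c(chr1 = random_dna(4000, g_prob = 0.2))))
  pat <- g4_preset("G3L1-7")
  motif <- "GGGTTAGGGTTAGGGTTAGGG"
  # plant motifs in two "peaks" only
  s <- g$sequences[["chr1"]]
  substr(s, 501, 521) <- motif
  substr(s, 1501, 1521) <- motif
  g <- genome(c(chr1 = s))
  peaks <- tibble::tibble(chrom = "chr1", start = c(480, 1480), end = c(540, 1540))
  ctrl <- sample_control_regions(peaks, g, n_per_peak = 30, seed = 1, genome = g)
  e <- motif_count_enrichment(peaks, ctrl, g, pat, seed = 1)
  expect_s3_class(e, "g4_enrichment")
  expect_gte(e$table[1, 1], 2)
  expect_gt(e$odds_ratio, 1)
  # uncovered bases = peak bases minus motif-covered bases (>= 2 x 21 bp here)
  expect_lte(e$table[1, 2], sum(peaks$end - peaks$start) - 2 * 21)

  p <- peak_presence_enrichment(peaks, ctrl, g, pat, seed = 1)
  expect_equal(p$table[1, ], c(with = 2, without = 0))
  # swapping peaks and controls inverts the odds ratio
  q <- peak_presence_enrichment(ctrl, peaks, g, pat, seed = 1)
  expect_equal(q$odds_ratio, 1 / p$odds_ratio, tolerance = 1e-12)

  td <- tidy(e)
  expect_equal(sum(td$count), sum(e$table))
  gl <- glance(p)
  expect_equal(gl$p_value, p$p_value)
})

test_that("degenerate presence columns give p = 1", {
  g <- genome(c(chr1 = strrep("GGGTTAGGGTTAGGGTTAGGGAATATATTAT", 40)))
  peaks <- tibble::tibble(chrom = "chr1", start = c(0, 31), end = c(31, 62))
  ctrl <- tibble::tibble(chrom = "chr1", start = c(62, 93), end = c(93, 124))
  expect_warning(p <- peak_presence_enrichment(peaks, ctrl, g, g4_preset("G3L1-7")),
                 "degenerate")
  expect_equal(p$p_value, 1)
})

test_that("bin enrichment flags concentrated ChIP signal and not flat signal", {
  sz <- c(chr1 = 50000) # 1000 bins of 50 bp
  flat <- tibble::tibble(chrom = "chr1", pos = seq(0, 49950, by = 50), length = 36)
  bins <- bin_track(flat, flat, sz)
  expect_equal(nrow(bins), 1000L)
  expect_equal(sum(bins$chip), 1000L)
  be <- bin_enrichment(bins)
  expect_equal(be$significant_fraction, 0)

  spike <- tibble::tibble(chrom = "chr1", pos = rep(10000, 1000), length = 36)
  be2 <- bin_enrichment(bin_track(spike, flat, sz))
  expect_equal(be2$significant_fraction, 0.001)
  expect_true(tidy(be2)$significant[tidy(be2)$bin_start == 10000])
  expect_gte(be2$significant_fraction, 0)
  expect_lte(be2$significant_fraction, 1)
  expect_error(bin_enrichment(bins[0, ]), "zero bins")
})

test_that("BH step-up matches the literal oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_fdr(c(0.5, 0.6), 0.05), c(FALSE, FALSE))
  expect_true(bh_fdr(0.05, 0.05)) # single p at alpha sits on the boundary
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  withr::with_seed(23, {
    for (i in 1:20) {
      p <- runif(sample.int(50, 1))^sample(c(1, 3), 1)
      expect_equal(bh_fdr(p, 0.1), oracle_bh(p, 0.1))
    }
  })
})
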