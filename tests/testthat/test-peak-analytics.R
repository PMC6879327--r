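pk <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start, end = end)

test_that("common_peaks applies the min-start/max-end rule", {
  out <- common_peaks(pk("chr1", 100, 200), pk("chr1", 150, 250))
  expect_equal(out$start, 100)
  expect_equal(out$end, 250)

  expect_equal(nrow(common_peaks(pk("chr1", 0, 50), pk("chr1", 60, 80))), 0L)

  # overlap chain A1-B1-A2 merges into a single component span
  out <- common_peaks(pk("chr1", c(0, 120), c(100, 200)), pk("chr1", 90, 130))
  expect_equal(out$start, 0)
  expect_equal(out$end, 200)

  # touching half-open intervals do not overlap
  expect_equal(nrow(common_peaks(pk("chr1", 0, 100), pk("chr1", 100, 200))), 0L)
})

test_that("common_peaks equals the connected-component oracle on random fixtures", {
  withr::with_seed(31, {
    for (i in 1:25) {
      r1 <- random_peaks(sample.int(60, 1))
      r2 <- random_peaks(sample.int(60, 1))
      got <- common_peaks(r1, r2)
      exp <- oracle_common_peaks(r1, r2)
      expect_equal(got$chrom, exp$chrom)
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      # outputs pairwise disjoint and each overlaps both replicates
      by_chrom <- split(got, got$chrom)
      for (d in by_chrom) {
        if (nrow(d) > 1) expect_true(all(d$start[-1] >= head(d$end, -1)))
      }
      for (j in seq_len(nrow(got))) {
        ov <- function(r) any(r$chrom == got$chrom[j] & r$start < got$end[j] &
                                got$start[j] < r$end)
        expect_true(ov(r1) && ov(r2))
      }
    }
  })
})

test_that("TSS proximity counts follow the distance thresholds", {
  tss <- tibble::tibble(gene = "g", chrom = "chr1", pos = 10000, strand = "+")
  counts <- tss_proximity_counts(pk("chr1", 4000, 4500), tss)
  expect_equal(counts$n_peaks, c(0L, 1L, 1L)) # 5 kb misses, 10/20 kb catch

  # a peak containing the TSS is counted at every threshold
  counts <- tss_proximity_counts(pk("chr1", 9000, 11000), tss, c(100, 5000, 20000))
  expect_equal(counts$n_peaks, c(1L, 1L, 1L))

  expect_warning(
    counts <- tss_proximity_counts(pk("chr1", 0, 10),
                                   tibble::tibble(chrom = character(), pos = numeric())),
    "empty"
  )
  expect_equal(counts$n_peaks, c(0L, 0L, 0L))
})

test_that("TSS counts are monotone in threshold and translation invariant", {
  withr::with_seed(62, {
    for (i in 1:10) {
      peaks <- random_peaks(50, max_pos = 100000)
      tss <- tibble::tibble(chrom = sample(c("chrA", "chrB"), 5, TRUE),
                            pos = sample.int(100000, 5))
      counts <- tss_proximity_counts(peaks, tss, c(5000, 10000, 20000))
      expect_true(all(diff(counts$n_peaks) >= 0))
      shift <- 12345
      shifted <- tss_proximity_counts(
        dplyr::mutate(peaks, start = start + shift, end = end + shift),
        dplyr::mutate(tss, pos = pos + shift), c(5000, 10000, 20000)
      )
      expect_equal(counts$n_peaks, shifted$n_peaks)
    }
  })
})

test_that("sub-telomeric classification uses both termini", {
  sz <- c(chr1 = 1e7)
  reads <- tibble::tibble(chrom = "chr1", pos = c(4e5, 5e6, 9.6e6), length = 36)
  out <- classify_subtelomeric(reads, sz)
  expect_equal(out$region, c("sub-telomeric", "interstitial", "sub-telomeric"))
  expect_error(classify_subtelomeric(tibble::tibble(chrom = "chrZ", pos = 1, length = 10), sz),
               "unknown chromosome")
})

test_that("read partition conserves per-chromosome totals", {
  sz <- c(chr1 = 2e6, chr2 = 4e6)
  withr::with_seed(8, {
    reads <- tibble::tibble(
      chrom = sample(names(sz), 300, TRUE, prob = c(0.3, 0.7)),
      length = 36
    )
    reads$pos <- floor(runif(300) * (sz[reads$chrom] - 36))
    part <- partition_read_counts(reads, sz)
    expect_equal(part$subtelomeric + part$interstitial,
                 as.integer(table(factor(reads$chrom, names(sz)))))
  })
  # margin covering half of each chromosome makes everything sub-telomeric
  part <- partition_read_counts(
    tibble::tibble(chrom = "chr1", pos = c(0, 1e6, 1.9e6), length = 36),
    sz, margin = 1e6
  )
  expect_equal(part$interstitial[part$chrom == "chr1"], 0L)
  # centre reads with a small margin are all interstitial
  part <- partition_read_counts(
    tibble::tibble(chrom = "chr1", pos = 1e6, length = 36), sz, margin = 1e4
  )
  expect_equal(part$subtelomeric[part$chrom == "chr1"], 0L)
})

test_that("telomeric repeat flags use both strands and preserve order", {
  g <- genome(c(chr1 = "AATTAGGGCCCCCTAACCACGTACGTAA"))
  peaks <- pk("chr1", c(0, 9, 20), c(9, 18, 28))
  out <- flag_telomeric_repeat_peaks(peaks, g)
  expect_equal(out$start, c(0, 9)) # TTAGGG peak then CCCTAA peak; ACGT peak dropped
  expect_error(flag_telomeric_repeat_peaks(pk("chr1", 0, 100), g), "beyond")
})

test_that("FRiP counts read midpoints and is order invariant", {
  peaks <- pk("chr1", 100, 200)
  reads <- tibble::tibble(chrom = "chr1", pos = c(90, 150, 195, 400), length = 20)
  # midpoints 100, 160, 205, 410 -> 2 of 4 inside
  expect_equal(frip(reads, peaks), 0.5)
  withr::with_seed(3, expect_equal(frip(reads[sample(4), ], peaks), 0.5))
  expect_equal(frip(reads, peaks[0, ]), 0)
  expect_equal(frip(dplyr::mutate(reads, pos = 150), peaks), 1)
  expect_error(frip(reads[0, ], peaks), "zero reads")
})

test_that("feature annotation follows the stated priority", {
  gm <- tibble::tibble(
    gene = "g1", chrom = "chr1", strand = "+", tx_start = 10000, tx_end = 20000,
    exon_starts = list(c(10000, 15000)), exon_ends = list(c(11000, 16000))
  )
  ann <- function(s, e, hw = 1000) {
    annotate_feature(pk("chr1", s, e), gm, promoter_halfwidth = hw)$feature
  }
  expect_equal(ann(8500, 9500), "promoter")     # midpoint 1 kb upstream of TSS
  expect_equal(ann(8500, 9500, hw = 10000), "promoter")
  expect_equal(ann(15200, 15400), "exon")
  expect_equal(ann(13000, 13500), "intron")
  expect_equal(ann(21000, 22000), "downstream") # within 5 kb past tx_end
  expect_equal(ann(40000, 41000), "intergenic")
  expect_equal(annotate_feature(pk("chr9", 0, 100), gm)$feature, "intergenic")
})
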