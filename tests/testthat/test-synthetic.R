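small_spec <- function(..., read_count = 2000) {
  synthetic_spec(n_chroms = 2, chrom_length = 20000, peak_count = 10,
                 peak_length = 250, read_count = read_count, ...)
}

test_that("generators are pure functions of spec and seed", {
  sp <- small_spec(seed = 123)
  a <- generate_genome(sp); b <- generate_genome(sp)
  expect_identical(a$genome$sequences, b$genome$sequences)
  expect_identical(a$motifs, b$motifs)
  fa1 <- withr::local_tempfile(); fa2 <- withr::local_tempfile()
  write_genome_fasta(a$genome, fa1); write_genome_fasta(b$genome, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  # a different seed changes the genome
  expect_false(identical(generate_genome(small_spec(seed = 124))$genome$sequences,
                         a$genome$sequences))
})

test_that("every planted motif is recovered verbatim by the scanner", {
  for (seed in c(1, 7, 19)) {
    sp <- small_spec(seed = seed, motif_density_background = 1.5)
    sim <- generate_genome(sp)
    for (cn in names(sim$genome$sequences)) {
      hits <- scan_pg4(sim$genome$sequences[[cn]], sp$pattern, "plus")
      m <- sim$motifs[sim$motifs$chrom == cn, ]
      expect_true(all(paste(m$start, m$end) %in% paste(hits$start, hits$end)))
      expect_true(all(m$sequence %in% hits$sequence))
    }
  }
})

test_that("sparse GC-poor background yields almost no spurious hits", {
  sp <- synthetic_spec(
    n_chroms = 1, chrom_length = 40000, peak_count = 5, peak_length = 250,
    motif_density_in_peaks = 0, motif_density_background = 0,
    base_composition = c(A = 0.3, C = 0.3, G = 0.1, T = 0.3), seed = 5
  )
  sim <- generate_genome(sp)
  n_hits <- count_pg4(sim$genome$sequences[[1]], sp$pattern, "plus")
  expect_lt(n_hits / (sp$chrom_length / 1000), 0.05) # hits per kb
})

test_that("replicates without jitter or decoys intersect back to the truth", {
  sp <- small_spec(replicate_jitter_sd = 0, false_positive_peaks = 0, seed = 2)
  sim <- generate_genome(sp)
  reps <- generate_replicate_peaks(sim$peaks, sp)
  common <- common_peaks(reps$rep1, reps$rep2)
  expect_equal(common$start, sim$peaks$start)
  expect_equal(common$end, sim$peaks$end)
})

test_that("decoys present in only one replicate never reach the common set", {
  sp <- small_spec(replicate_jitter_sd = 0, false_positive_peaks = 8, seed = 11)
  sim <- generate_genome(sp)
  reps <- generate_replicate_peaks(sim$peaks, sp)
  # drop rep2's decoys so its peaks are exactly the truth
  rep2 <- reps$rep2[paste(reps$rep2$chrom, reps$rep2$start) %in%
                      paste(sim$peaks$chrom, sim$peaks$start), ]
  common <- common_peaks(reps$rep1, rep2)
  # every common peak must contain a true peak; count matches the truth
  expect_equal(nrow(common), nrow(sim$peaks))
})

test_that("jittered replicates recover at least 95% of true peaks", {
  recovered <- vapply(1:20, function(seed) {
    sp <- small_spec(seed = 700 + seed) # jitter_sd 15 < peak_length/10
    sim <- generate_genome(sp)
    reps <- generate_replicate_peaks(sim$peaks, sp)
    common <- common_peaks(reps$rep1, reps$rep2)
    hit <- vapply(seq_len(nrow(sim$peaks)), function(i) {
      any(common$chrom == sim$peaks$chrom[i] & common$start < sim$peaks$end[i] &
            sim$peaks$start[i] < common$end)
    }, logical(1))
    mean(hit)
  }, numeric(1))
  expect_gte(mean(recovered), 0.95)
})

test_that("telomeric read fraction matches the binomial target", {
  sp <- small_spec(seed = 42)
  sim <- generate_genome(sp)
  rd <- generate_reads(sim$genome, sim$peaks, sp)
  frac <- mean(is_telomeric_read(rd$reads))
  # every synthetic telomeric read is detected; background reads rarely match
  expect_true(all(is_telomeric_read(rd$reads[rd$telomeric])))
  expect_equal(frac, mean(rd$telomeric), tolerance = 0.01)
  se3 <- 3 * sqrt(0.23 * 0.77 / sp$read_count)
  expect_lt(abs(frac - 0.23), se3 + 0.005)
})

test_that("uniform read rate gives FRiP near the peak length share", {
  sp <- small_spec(peak_read_fold = 1, read_count = 8000, seed = 9)
  sim <- generate_genome(sp)
  rd <- generate_reads(sim$genome, sim$peaks, sp)
  share <- sum(sim$peaks$end - sim$peaks$start) / sum(sim$genome$sizes)
  expect_equal(frip(rd$placements, sim$peaks), share, tolerance = 0.35)
  # strong enrichment pushes FRiP far above the share
  sp10 <- small_spec(peak_read_fold = 10, read_count = 8000, seed = 9)
  rd10 <- generate_reads(sim$genome, sim$peaks, sp10)
  expect_gt(frip(rd10$placements, sim$peaks), 3 * share)
})

test_that("read enrichment concentrates significant bins in peaks", {
  sp <- small_spec(peak_read_fold = 25, read_count = 20000,
                   telomeric_fraction = 0, seed = 13)
  sim <- generate_genome(sp)
  chip <- generate_reads(sim$genome, sim$peaks, sp)$placements
  sp_in <- small_spec(peak_read_fold = 1, read_count = 20000,
                      telomeric_fraction = 0, seed = 14)
  input <- generate_reads(sim$genome, sim$peaks, sp_in)$placements
  be <- bin_enrichment(bin_track(chip, input, sim$genome))
  expect_gt(be$significant_fraction, 0)
  sig <- tidy(be)[tidy(be)$significant, ]
  in_peak <- vapply(seq_len(nrow(sig)), function(i) {
    any(sim$peaks$chrom == sig$chrom[i] & sim$peaks$start < sig$bin_start[i] + 50 &
          sig$bin_start[i] < sim$peaks$end)
  }, logical(1))
  expect_gt(mean(in_peak), 0.9)
})

test_that("synthetic FID titrations return the truth at zero noise", {
  s <- generate_fid_series(3, hill = 1.5, noise_cv = 0, seed = 1)
  expect_equal(dc50(s), 3, tolerance = 0.02)
  expect_error(generate_fid_series(-1), "dc50_true")
  low <- generate_fid_series(10, concentrations = c(0.5, 1, 2), noise_cv = 0, seed = 1)
  expect_error(dc50(low), "not reached")
})

test_that("spec validation rejects malformed parameters", {
  expect_error(synthetic_spec(base_composition = c(A = 0.5, C = 0.5, G = 0, T = 0.1)),
               "sum to 1")
  expect_error(synthetic_spec(telomeric_fraction = 1.2), "telomeric_fraction")
  expect_error(synthetic_spec(replicate_jitter_sd = -1), ">= 0")
})
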