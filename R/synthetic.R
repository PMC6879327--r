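#' Specification of a synthetic study
#'
#' Bundles every parameter of the synthetic-data generators: a
#' multi-chromosome i.i.d. background genome, true binding peaks, PG4
#' motifs planted at different densities inside and outside peaks,
#' jittered replicate peak calls with decoys, short reads with a
#' controlled telomeric fraction and in-peak enrichment, and noisy
#' sigmoidal G4-FID titrations. Defaults emulate a desk-scale version of
#' a TRF2-style ChIP-Seq experiment: ~300-bp peaks (sonicated chromatin
#' fragment size), 36-bp reads, a 23% telomeric read fraction, and a
#' 5-fold PG4 planting excess inside peaks.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param base_composition Named probabilities over `A`, `C`, `G`, `T`
#'   summing to 1.
#' @param peak_count Number of true peaks genome-wide.
#' @param peak_length Peak length (bp).
#' @param motif_density_in_peaks,motif_density_background Expected planted
#'   motifs per kb inside/outside peaks.
#' @param pattern [g4_pattern()] used to construct planted motifs.
#' @param replicate_jitter_sd SD (bp) of the Normal endpoint jitter
#'   applied to each replicate.
#' @param false_positive_peaks Decoy peaks added per replicate.
#' @param read_count Total reads.
#' @param read_length Read length (bp).
#' @param telomeric_fraction Fraction of reads replaced by tandem
#'   `TTAGGG` repeats.
#' @param peak_read_fold Read start-rate fold inside peaks.
#' @param seed Root integer seed; each generator derives a stage seed
#'   from it.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_chroms = 2,
                           chrom_length = 50000,
                           base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           peak_count = 30,
                           peak_length = 300,
                           motif_density_in_peaks = 2.5,
                           motif_density_background = 0.5,
                           pattern = g4_preset("G3L1-7"),
                           replicate_jitter_sd = 15,
                           false_positive_peaks = 5,
                           read_count = 10000,
                           read_length = 36,
                           telomeric_fraction = 0.23,
                           peak_read_fold = 10,
                           seed = 1) {
  stopifnot(inherits(pattern, "g4_pattern"))
  if (abs(sum(base_composition) - 1) > 1e-9) abort("base_composition must sum to 1")
  if (!setequal(names(base_composition), c("A", "C", "G", "T"))) {
    abort("base_composition must be named over A, C, G, T")
  }
  if (telomeric_fraction < 0 || telomeric_fraction > 1) abort("telomeric_fraction must be in [0, 1]")
  counts <- c(n_chroms, chrom_length, peak_count, peak_length,
              false_positive_peaks, read_count, read_length)
  if (any(counts < 0)) abort("counts and lengths must be >= 0")
  if (replicate_jitter_sd < 0 || motif_density_in_peaks < 0 || motif_density_background < 0) {
    abort("rates and jitter must be >= 0")
  }
  structure(
    list(n_chroms = n_chroms, chrom_length = chrom_length,
         base_composition = base_composition[c("A", "C", "G", "T")],
         peak_count = peak_count, peak_length = peak_length,
         motif_density_in_peaks = motif_density_in_peaks,
         motif_density_background = motif_density_background,
         pattern = pattern, replicate_jitter_sd = replicate_jitter_sd,
         false_positive_peaks = false_positive_peaks,
         read_count = read_count, read_length = read_length,
         telomeric_fraction = telomeric_fraction,
         peak_read_fold = peak_read_fold, seed = seed),
    class = "synthetic_spec"
  )
}

# Derive a deterministic per-stage seed below 2^31 from the root seed
# and a stage name. A polynomial rolling hash keeps distinct stage names
# (e.g. "replicate12" vs "replicate21") on distinct streams; all
# intermediate products stay below 2^53 so the arithmetic is exact.
stage_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  ((as.numeric(seed) %% m) * 48271 + h) %% m
}

spec_sizes <- function(spec) {
  setNames(rep(spec$chrom_length, spec$n_chroms), paste0("chr", seq_len(spec$n_chroms)))
}

# Build one planted motif: n_runs G-tracts of run_len with loops drawn
# uniformly in [loop_min, loop_max] over {A, C, T} (never G, so loops can
# not extend a tract).
build_motif <- function(pattern) {
  tract <- strrep("G", pattern$run_len)
  loops <- vapply(seq_len(pattern$n_runs - 1), function(i) {
    n <- pattern$loop_min + sample.int(pattern$loop_max - pattern$loop_min + 1, 1) - 1
    paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  paste0(paste0(tract, c(loops, "")), collapse = "")
}

# A planting site is admissible when the motif's flanks are not G and a
# guard window of loop_max + run_len bp on each side holds no qualifying
# G-run, so the planted hit is exactly what the scanner recovers.
site_ok <- function(chars, s, e, w, run_len) {
  L <- length(chars)
  if (s > 1 && chars[s - 1] == "G") return(FALSE)
  if (e < L && chars[e + 1] == "G") return(FALSE)
  win <- c(max(1, s - w):max(1, s - 1), min(L, e + 1):min(L, e + w))
  win <- win[win >= 1 & win <= L & (win < s | win > e)]
  if (!length(win)) return(TRUE)
  r <- rle(chars[sort(unique(win))] == "G")
  !any(r$values & r$lengths >= run_len)
}

plant_motifs <- function(chars, n, lo, hi, pattern, planted, forbid, w, tries = 200) {
  # plant n motifs with starts in [lo, hi] (1-based), avoiding intervals in
  # `forbid` entirely and keeping a > w gap to previously planted motifs
  out <- list()
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(tries)) {
      motif <- build_motif(pattern)
      ml <- nchar(motif)
      if (hi - ml + 1 < lo) break
      s <- lo + sample.int(hi - ml + 1 - lo + 1, 1) - 1
      e <- s + ml - 1
      if (nrow(forbid) && any(forbid$s <= e & s <= forbid$e)) next
      if (length(planted$s) && any(planted$s - w <= e & s <= planted$e + w)) next
      if (!site_ok(chars, s, e, w, pattern$run_len)) next
      chars[s:e] <- strsplit(motif, "")[[1]]
      planted$s <- c(planted$s, s); planted$e <- c(planted$e, e)
      planted$seq <- c(planted$seq, motif)
      placed <- TRUE
      break
    }
    if (!placed) abort("could not place a planted motif within the retry budget")
  }
  list(chars = chars, planted = planted)
}

#' Generate a synthetic genome with planted peaks and PG4 motifs
#'
#' Background bases are i.i.d. from `base_composition`; true peaks are
#' placed uniformly without overlap; motifs are planted at Poisson rates
#' given by the in-peak/background densities, at sites where flanking
#' guard windows guarantee each planted motif is recovered verbatim by
#' [scan_pg4()] with its generating pattern.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `genome` ([genome()]), `peaks` (true-peak
#'   tibble) and `motifs` (ground-truth motif tibble with `chrom`,
#'   `start`, `end`, `sequence`, `in_peak`).
#' @export
generate_genome <- function(spec) {
  withr::with_seed(stage_seed(spec$seed, "genome"), {
    sizes <- spec_sizes(spec)
    w <- spec$pattern$loop_max + spec$pattern$run_len
    # place true peaks genome-wide, uniform and non-overlapping
    peaks <- tibble(chrom = character(), start = numeric(), end = numeric())
    for (i in seq_len(spec$peak_count)) {
      done <- FALSE
      for (t in seq_len(1000)) {
        cn <- sample(names(sizes), 1, prob = sizes)
        s <- sample.int(sizes[[cn]] - spec$peak_length + 1, 1) - 1
        e <- s + spec$peak_length
        if (!any(peaks$chrom == cn & peaks$start < e & s < peaks$end)) {
          peaks <- dplyr::bind_rows(peaks, tibble(chrom = cn, start = s, end = e))
          done <- TRUE
          break
        }
      }
      if (!done) abort("could not place non-overlapping peaks within the retry budget")
    }
    peaks <- dplyr::arrange(peaks, .data$chrom, .data$start)
    peaks$name <- sprintf("true_%d", seq_len(nrow(peaks)))

    seqs <- character(0)
    motifs <- list()
    for (cn in names(sizes)) {
      chars <- sample(names(spec$base_composition), sizes[[cn]], replace = TRUE,
                      prob = spec$base_composition)
      pk <- peaks[peaks$chrom == cn, ]
      planted <- list(s = numeric(0), e = numeric(0), seq = character(0))
      # inside each peak
      for (j in seq_len(nrow(pk))) {
        n <- rpois(1, spec$motif_density_in_peaks * (pk$end[j] - pk$start[j]) / 1000)
        res <- plant_motifs(chars, n, pk$start[j] + 1, pk$end[j], spec$pattern,
                            planted, tibble(s = numeric(0), e = numeric(0)), w)
        chars <- res$chars; planted <- res$planted
      }
      n_in_peak_motifs <- length(planted$s)
      # background: anywhere fully outside peaks
      bg_len <- sizes[[cn]] - sum(pk$end - pk$start)
      n_bg <- rpois(1, spec$motif_density_background * bg_len / 1000)
      forbid <- tibble(s = pk$start + 1, e = pk$end)
      res <- plant_motifs(chars, n_bg, 1, sizes[[cn]], spec$pattern, planted, forbid, w)
      chars <- res$chars; planted <- res$planted
      seqs[[cn]] <- paste(chars, collapse = "")
      if (length(planted$s)) {
        motifs[[cn]] <- tibble(
          chrom = cn, start = planted$s - 1, end = planted$e,
          sequence = planted$seq,
          in_peak = seq_along(planted$s) <= n_in_peak_motifs
        )
      }
    }
    motifs <- dplyr::bind_rows(motifs)
    if (nrow(motifs)) motifs <- dplyr::arrange(motifs, .data$chrom, .data$start)
    list(genome = genome(seqs), peaks = peaks, motifs = motifs)
  })
}

#' Generate jittered replicate peak calls
#'
#' Each replicate is the true peak set with both endpoints shifted by
#' rounded `Normal(0, replicate_jitter_sd)` noise (clamped to the
#' chromosome), plus `false_positive_peaks` uniformly placed decoys.
#'
#' @param true_peaks True-peak tibble from [generate_genome()].
#' @param spec A [synthetic_spec()].
#' @return A list with tibbles `rep1` and `rep2`.
#' @export
generate_replicate_peaks <- function(true_peaks, spec) {
  withr::with_seed(stage_seed(spec$seed, "replicates"), {
    sizes <- spec_sizes(spec)
    one_rep <- function(tag) {
      s <- true_peaks$start + round(rnorm(nrow(true_peaks), 0, spec$replicate_jitter_sd))
      e <- true_peaks$end + round(rnorm(nrow(true_peaks), 0, spec$replicate_jitter_sd))
      s <- pmax(0, pmin(s, sizes[true_peaks$chrom] - 2))
      e <- pmax(s + 1, pmin(e, sizes[true_peaks$chrom]))
      jittered <- tibble(chrom = true_peaks$chrom, start = s, end = e)
      decoys <- purrr::map_dfr(seq_len(spec$false_positive_peaks), function(i) {
        cn <- sample(names(sizes), 1, prob = sizes)
        ds <- sample.int(sizes[[cn]] - spec$peak_length + 1, 1) - 1
        tibble(chrom = cn, start = ds, end = ds + spec$peak_length)
      })
      dplyr::bind_rows(jittered, decoys) |>
        dplyr::arrange(.data$chrom, .data$start) |>
        dplyr::mutate(name = sprintf("%s_%d", tag, dplyr::row_number()))
    }
    list(rep1 = one_rep("rep1"), rep2 = one_rep("rep2"))
  })
}

#' Generate reads with in-peak enrichment and a telomeric fraction
#'
#' Read starts follow a two-rate model: the start rate inside true peaks
#' is `peak_read_fold` times the background rate. A `telomeric_fraction`
#' of reads (Bernoulli per read) have their sequence replaced by tandem
#' `TTAGGG` repeats at a random phase; their placements are retained so
#' FRiP and bin ground truth stay intact.
#'
#' @param genome A [genome()].
#' @param true_peaks True-peak tibble.
#' @param spec A [synthetic_spec()].
#' @return A list with `reads` (character vector), `placements` (tibble
#'   `chrom`, `pos`, `length`) and `telomeric` (logical ground truth).
#' @export
generate_reads <- function(genome, true_peaks, spec) {
  withr::with_seed(stage_seed(spec$seed, "reads"), {
    sizes <- genome$sizes
    if (spec$read_length > min(sizes)) abort("read_length exceeds a chromosome length")
    weights <- lapply(names(sizes), function(cn) {
      n_pos <- sizes[[cn]] - spec$read_length + 1
      w <- rep(1, n_pos)
      pk <- true_peaks[true_peaks$chrom == cn, ]
      for (j in seq_len(nrow(pk))) {
        lo <- max(1, pk$start[j] + 1)
        hi <- min(n_pos, pk$end[j])
        if (lo <= hi) w[lo:hi] <- spec$peak_read_fold
      }
      w
    })
    names(weights) <- names(sizes)
    totals <- vapply(weights, sum, numeric(1))
    n_per_chrom <- as.vector(stats::rmultinom(1, spec$read_count, totals))
    placements <- purrr::map2_dfr(names(sizes), n_per_chrom, function(cn, n) {
      if (n == 0) return(tibble(chrom = character(), pos = numeric(), length = numeric()))
      pos <- sample.int(length(weights[[cn]]), n, replace = TRUE, prob = weights[[cn]]) - 1
      tibble(chrom = cn, pos = pos, length = spec$read_length)
    })
    reads <- region_sequence(genome, dplyr::transmute(
      placements, chrom = .data$chrom, start = .data$pos, end = .data$pos + .data$length))
    telomeric <- runif(nrow(placements)) < spec$telomeric_fraction
    if (any(telomeric)) {
      phase <- sample.int(6, sum(telomeric), replace = TRUE) - 1
      tandem <- strrep("TTAGGG", ceiling((spec$read_length + 5) / 6) + 1)
      reads[telomeric] <- substring(tandem, phase + 1, phase + spec$read_length)
    }
    list(reads = reads, placements = placements, telomeric = telomeric)
  })
}

#' Generate a noisy sigmoidal G4-FID titration
#'
#' Fluorescence areas follow `FAx = FA1 (1 - Hill(c)/100)(1 + eps)` with
#' `Hill(c) = 100 c^h / (c^h + DC50^h)` and `eps ~ Normal(0, noise_cv)`;
#' the baseline point `(0, FA1)` is noise-free.
#'
#' @param dc50_true True DC50 (> 0, molar equivalents).
#' @param hill Hill coefficient of the generating curve.
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param concentrations Titrant amounts; defaults to a geometric-ish
#'   ladder spanning 0.25-4x the true DC50 (plus the 0 baseline).
#' @param seed Integer seed.
#' @param fa1 Baseline fluorescence area.
#' @return A [fid_series()] tibble.
#' @export
generate_fid_series <- function(dc50_true, hill = 1, noise_cv = 0.02,
                                concentrations = NULL, seed = 1, fa1 = 1000) {
  if (dc50_true <= 0) abort("dc50_true must be > 0")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  conc <- concentrations %||% (dc50_true * c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4))
  conc <- sort(unique(conc[conc > 0]))
  withr::with_seed(stage_seed(seed, "fid"), {
    h <- 100 * conc^hill / (conc^hill + dc50_true^hill)
    eps <- rnorm(length(conc), 0, noise_cv)
    fa <- pmax(0, fa1 * (1 - h / 100) * (1 + eps))
    fid_series(c(0, conc), c(fa1, fa))
  })
}
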