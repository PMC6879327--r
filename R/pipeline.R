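#' Configure an end-to-end quadchip run
#'
#' A configuration either carries a [synthetic_spec()] (everything is
#' simulated) or paths to real inputs (FASTA genome, two replicate BED
#' files, optional TSS table, optional read files). Every stage draws its
#' randomness from `seed`, split per stage by stable stage names, so a
#' configuration is fully reproducible.
#'
#' @param spec Optional [synthetic_spec()]; when present all inputs are
#'   generated.
#' @param fasta,rep1,rep2 Paths to the genome FASTA and replicate peak
#'   BED files (required when `spec` is `NULL`).
#' @param tss Optional TSS tibble or path to a TSS table
#'   ([read_tss_table()] format).
#' @param reads,placements Optional paths: read sequences (one per line)
#'   and their placements (TSV `chrom`, `pos`, `length`).
#' @param pattern [g4_pattern()] used for enrichment tests.
#' @param n_controls_per_peak Control regions per peak (default 100).
#' @param fdr FDR level for bin enrichment.
#' @param bin_size Bin width in bp.
#' @param subtelomeric_margin Sub-telomeric margin in bp.
#' @param tss_thresholds TSS proximity thresholds in bp.
#' @param seed Root integer seed.
#' @return A `quadchip_config` list.
#' @export
quadchip_config <- function(spec = NULL, fasta = NULL, rep1 = NULL, rep2 = NULL,
                            tss = NULL, reads = NULL, placements = NULL,
                            pattern = g4_preset("G3L1-7"),
                            n_controls_per_peak = 100, fdr = 0.05,
                            bin_size = 50, subtelomeric_margin = 5e5,
                            tss_thresholds = c(5000, 10000, 20000),
                            seed = 1) {
  cfg <- structure(
    list(spec = spec, fasta = fasta, rep1 = rep1, rep2 = rep2, tss = tss,
         reads = reads, placements = placements, pattern = pattern,
         n_controls_per_peak = n_controls_per_peak, fdr = fdr,
         bin_size = bin_size, subtelomeric_margin = subtelomeric_margin,
         tss_thresholds = tss_thresholds, seed = seed),
    class = "quadchip_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$spec)) {
    for (f in c("fasta", "rep1", "rep2")) {
      if (is.null(cfg[[f]])) abort(sprintf("config: '%s' path is required without a synthetic spec", f))
      if (!file.exists(cfg[[f]])) abort(sprintf("config: %s file '%s' does not exist", f, cfg[[f]]))
    }
  } else {
    stopifnot(inherits(cfg$spec, "synthetic_spec"))
  }
  for (f in c("reads", "placements")) {
    if (!is.null(cfg[[f]]) && is.character(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(sprintf("config: %s file '%s' does not exist", f, cfg[[f]]))
    }
  }
  if (!is.null(cfg$tss) && is.character(cfg$tss) && !file.exists(cfg$tss)) {
    abort(sprintf("config: tss file '%s' does not exist", cfg$tss))
  }
  if (any(cfg$tss_thresholds <= 0)) abort("config: tss_thresholds must be positive")
  stopifnot(inherits(cfg$pattern, "g4_pattern"))
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes the whole analysis on the configured inputs: replicate peak
#' intersection, PG4 scanning, both enrichment tests against
#' length-matched random controls, TSS proximity (when a TSS table is
#' available), telomeric read classification and sub-telomeric/
#' interstitial partition, FRiP and bin-level ChIP-vs-input enrichment.
#' Identical configuration and seed give identical results (the JSON
#' summary differs only in its `timestamp` field).
#'
#' @param config A [quadchip_config()].
#' @param out_dir Optional directory; when given, writes `summary.json`,
#'   `common_peaks.tsv` and, when reads are present, `read_partition.tsv`.
#' @return The summary list, invisibly classed `quadchip_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_config(config)
  summary <- list(
    parameters = list(
      pattern = config$pattern$name,
      n_controls_per_peak = config$n_controls_per_peak,
      fdr = config$fdr, bin_size = config$bin_size,
      subtelomeric_margin = config$subtelomeric_margin,
      seed = config$seed
    ),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  if (!is.null(config$spec)) {
    sim <- generate_genome(config$spec)
    gen <- sim$genome
    reps <- generate_replicate_peaks(sim$peaks, config$spec)
    rep1 <- reps$rep1; rep2 <- reps$rep2
    rd <- generate_reads(gen, sim$peaks, config$spec)
    reads <- rd$reads; placements <- rd$placements
    input_placements <- withr::with_seed(
      stage_seed(config$spec$seed, "input"),
      {
        spec0 <- config$spec
        spec0$peak_read_fold <- 1
        spec0$telomeric_fraction <- 0
        generate_reads(gen, sim$peaks, spec0)$placements
      }
    )
  } else {
    gen <- read_genome_fasta(config$fasta)
    rep1 <- read_bed(config$rep1, sizes = gen)
    rep2 <- read_bed(config$rep2, sizes = gen)
    reads <- if (!is.null(config$reads)) readLines(config$reads)
    placements <- if (!is.null(config$placements)) {
      readr::read_tsv(config$placements, col_types = readr::cols(
        chrom = "c", pos = "d", length = "d"), progress = FALSE)
    }
    input_placements <- NULL
  }

  common <- common_peaks(rep1, rep2)
  summary$common_peaks <- list(n_rep1 = nrow(rep1), n_rep2 = nrow(rep2),
                               n_common = nrow(common))

  controls <- sample_control_regions(
    common, gen, n_per_peak = config$n_controls_per_peak,
    seed = stage_seed(config$seed, "controls"), genome = gen
  )
  enr_count <- motif_count_enrichment(common, controls, gen, config$pattern,
                                      seed = config$seed)
  enr_pres <- peak_presence_enrichment(common, controls, gen, config$pattern,
                                       seed = config$seed)
  summary$enrichment <- list(
    motif_count = as.list(glance(enr_count)),
    peak_presence = as.list(glance(enr_pres))
  )
  summary$telomeric_repeat_peaks <- nrow(flag_telomeric_repeat_peaks(common, gen))

  tss <- config$tss
  if (is.character(tss)) tss <- read_tss_table(tss)
  if (!is.null(tss)) {
    counts <- tss_proximity_counts(common, tss, config$tss_thresholds)
    summary$tss_proximity <- setNames(as.list(counts$n_peaks),
                                      paste0("within_", counts$threshold, "bp"))
  }

  partition <- NULL
  if (!is.null(reads) && length(reads)) {
    summary$reads <- list(
      n = length(reads),
      telomeric_fraction = mean(is_telomeric_read(reads))
    )
  }
  if (!is.null(placements) && nrow(placements)) {
    partition <- partition_read_counts(placements, gen, config$subtelomeric_margin)
    summary$read_partition <- list(
      subtelomeric = sum(partition$subtelomeric),
      interstitial = sum(partition$interstitial)
    )
    summary$frip <- frip(placements, common)
    if (!is.null(input_placements)) {
      bins <- bin_track(placements, input_placements, gen, config$bin_size)
      be <- bin_enrichment(bins, config$fdr)
      summary$bins <- list(n_bins = nrow(be$bins),
                           significant_fraction = be$significant_fraction)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_tsv(common, file.path(out_dir, "common_peaks.tsv"))
    if (!is.null(partition)) {
      readr::write_tsv(partition, file.path(out_dir, "read_partition.tsv"))
    }
  }
  invisible(structure(summary, class = "quadchip_report"))
}
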