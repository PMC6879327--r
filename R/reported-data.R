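#' Reported summary statistics of the motivating TRF2 ChIP-Seq study
#'
#' Transcribed published summary counts from the extra-telomeric TRF2
#' ChIP-Seq experiment that motivated this package: total/aligned/
#' telomeric read counts, per-replicate peak counts and reads-in-peaks,
#' common and high-confidence (IDR <= 0.01) peak counts, TSS-proximity
#' counts, TTAGGG-containing peak count, the enriched-bin percentage,
#' and the percentages as printed. Genome-scale quantities like these
#' require the deposited raw reads and a full alignment/peak-calling
#' stack to recompute; here they serve as reference values for
#' arithmetic-consistency checks and for parameterising the synthetic
#' generator (e.g. the 23% telomeric read fraction).
#'
#' @return A tibble with columns `metric` and `value`.
#' @export
trf2_reported_stats <- function() {
  readr::read_tsv(system.file("extdata", "trf2_reported_stats.tsv", package = "quadchip"),
                  col_types = readr::cols(metric = "c", value = "d"), progress = FALSE)
}

#' Reported sub-telomeric / interstitial read partition
#'
#' The published per-chromosome partition of aligned TRF2 ChIP-Seq reads
#' into sub-telomeric (within 0.5 Mb of a chromosome terminus) and
#' interstitial compartments, averaged over two replicates (hence the
#' half counts).
#'
#' @return A tibble with columns `chrom`, `subtelomeric`, `interstitial`.
#' @export
trf2_read_partition <- function() {
  readr::read_tsv(system.file("extdata", "trf2_read_partition.tsv", package = "quadchip"),
                  col_types = readr::cols(chrom = "c", subtelomeric = "d",
                                          interstitial = "d"), progress = FALSE)
}

#' Path to the CTCF negative-control sequence
#'
#' A 156-bp CTCF-site sequence used as a PG4-free negative control in
#' TRF2 ChIP experiments; it contains no qualifying PG4 motif on either
#' strand and is useful for exercising [scan_pg4()].
#'
#' @return Path to a FASTA file shipped with the package.
#' @export
ctcf_control_fasta <- function() {
  system.file("extdata", "ctcf_negative_control.fa", package = "quadchip")
}
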