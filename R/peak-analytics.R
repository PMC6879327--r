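#' Common peaks between two replicate peak sets
#'
#' Pools both replicates, finds maximal connected components of the
#' interval-overlap graph per chromosome, and for every component that
#' contains at least one peak from each replicate emits a single peak
#' spanning `[min(starts), max(ends))` — the min-start/max-end rule for
#' intersecting replicate coordinates, generalised to overlap chains.
#' Peaks overlapping only within one replicate emit nothing.
#'
#' @param rep1,rep2 Peak tibbles (`chrom`, `start`, `end`, ...).
#' @return A tibble of disjoint common peaks sorted by `(chrom, start)`,
#'   with a `name` column `common_<i>`.
#' @export
common_peaks <- function(rep1, rep2) {
  check_intervals(rep1, "rep1"); check_intervals(rep2, "rep2")
  pooled <- dplyr::bind_rows(
    dplyr::mutate(rep1[c("chrom", "start", "end")], rep = 1L),
    dplyr::mutate(rep2[c("chrom", "start", "end")], rep = 2L)
  )
  if (!nrow(pooled)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character()))
  }
  out <- pooled |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      # a new component begins where an interval starts at or past the
      # running maximum end (half-open: touching intervals do not overlap)
      d$comp <- cumsum(d$start >= dplyr::lag(cummax(as.numeric(d$end)), default = -Inf))
      d |>
        dplyr::group_by(.data$comp) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         both = dplyr::n_distinct(.data$rep) == 2L,
                         .groups = "drop") |>
        dplyr::filter(.data$both) |>
        dplyr::select("start", "end")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start)
  dplyr::mutate(out, name = sprintf("common_%d", dplyr::row_number()))
}

# Minimum distance from each peak to any TSS on its chromosome (Inf when
# the chromosome carries no TSS).
min_tss_distance <- function(peaks, tss) {
  vapply(seq_len(nrow(peaks)), function(i) {
    pos <- tss$pos[tss$chrom == peaks$chrom[i]]
    if (!length(pos)) return(Inf)
    min(interval_distance(peaks$start[i], peaks$end[i], pos))
  }, numeric(1))
}

#' Count peaks within distance thresholds of a TSS
#'
#' A peak is counted at threshold `d` when the minimum
#' [interval_distance()] from the peak to any TSS on its chromosome is at
#' most `d`; a peak containing a TSS has distance 0 and is counted at
#' every threshold. Counts are therefore non-decreasing in the threshold.
#'
#' @param peaks Peak tibble.
#' @param tss TSS tibble (`chrom`, `pos`, ...), e.g. from
#'   [read_tss_table()].
#' @param thresholds Positive distance thresholds in bp.
#' @return A tibble with columns `threshold` and `n_peaks`.
#' @export
tss_proximity_counts <- function(peaks, tss, thresholds = c(5000, 10000, 20000)) {
  check_intervals(peaks)
  if (any(thresholds <= 0)) abort("thresholds must be positive")
  if (!nrow(tss)) {
    warn("empty TSS list: all proximity counts are 0")
    return(tibble(threshold = sort(thresholds), n_peaks = 0L))
  }
  d <- min_tss_distance(peaks, tss)
  tibble(threshold = sort(thresholds)) |>
    dplyr::mutate(n_peaks = vapply(.data$threshold, function(t) sum(d <= t), integer(1)))
}

#' Classify intervals or read placements as sub-telomeric or interstitial
#'
#' An item is sub-telomeric when any of its bases lies within `margin` of
#' position 0 or of the chromosome end; everything else is interstitial.
#' Accepts peak-style tibbles (`chrom`, `start`, `end`) or read placements
#' (`chrom`, `pos`, `length`).
#'
#' @param x Tibble of intervals or read placements.
#' @param sizes Chromosome sizes (tibble, named vector or [genome()]).
#' @param margin Terminal margin in bp (default 0.5 Mb).
#' @return `x` with an added `region` column (`"sub-telomeric"` /
#'   `"interstitial"`).
#' @export
classify_subtelomeric <- function(x, sizes, margin = 5e5) {
  sz <- sizes_vec(sizes)
  if (!all(c("start", "end") %in% names(x))) {
    if (!all(c("pos", "length") %in% names(x))) {
      abort("x needs columns chrom+start+end or chrom+pos+length")
    }
    x$start <- x$pos
    x$end <- x$pos + x$length
  }
  unknown <- setdiff(unique(x$chrom), names(sz))
  if (length(unknown)) abort(sprintf("unknown chromosome '%s'", unknown[1]))
  len <- sz[x$chrom]
  sub <- unname(x$start < margin | x$end > len - margin)
  dplyr::mutate(x, region = ifelse(sub, "sub-telomeric", "interstitial"))
}

#' Partition read counts into sub-telomeric and interstitial compartments
#'
#' @param reads Read placement tibble (`chrom`, `pos`, `length`).
#' @param sizes Chromosome sizes.
#' @param margin Terminal margin in bp (default 0.5 Mb).
#' @return A tibble with one row per chromosome in `sizes` and columns
#'   `chrom`, `subtelomeric`, `interstitial`; row sums equal the number of
#'   input reads on each chromosome.
#' @export
partition_read_counts <- function(reads, sizes, margin = 5e5) {
  sz <- sizes_vec(sizes)
  cls <- classify_subtelomeric(reads, sz, margin)
  counts <- cls |>
    dplyr::count(.data$chrom, .data$region) |>
    tidyr::pivot_wider(names_from = "region", values_from = "n", values_fill = 0L)
  out <- tibble(chrom = names(sz)) |>
    dplyr::left_join(counts, by = "chrom")
  for (col in c("sub-telomeric", "interstitial")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out |>
    dplyr::transmute(.data$chrom,
                     subtelomeric = dplyr::coalesce(.data$`sub-telomeric`, 0L),
                     interstitial = dplyr::coalesce(.data$interstitial, 0L))
}

#' Flag peaks containing a telomeric repeat unit
#'
#' Keeps the peaks whose sequence carries at least one `TTAGGG` on either
#' strand (a `CCCTAA` on the plus strand is a minus-strand unit). Order is
#' preserved.
#'
#' @param peaks Peak tibble.
#' @param genome A [genome()] covering the peaks.
#' @return The flagged subset of `peaks`.
#' @export
flag_telomeric_repeat_peaks <- function(peaks, genome) {
  seqs <- region_sequence(genome, peaks)
  keep <- lengths(lapply(seqs, find_telomeric_tracts)) > 0 |
    lengths(lapply(vapply(seqs, revcomp, character(1)), find_telomeric_tracts)) > 0
  peaks[keep, , drop = FALSE]
}

#' Fraction of reads in peaks (FRiP)
#'
#' A read belongs to a peak when its midpoint, `pos + floor(length / 2)`,
#' lies inside the peak. Overlapping peaks are merged before counting.
#'
#' @param reads Read placement tibble (`chrom`, `pos`, `length`).
#' @param peaks Peak tibble.
#' @return The fraction in `[0, 1]`.
#' @export
frip <- function(reads, peaks) {
  if (!nrow(reads)) abort("FRiP is undefined for zero reads")
  if (!nrow(peaks)) return(0)
  check_intervals(peaks)
  merged <- peaks |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(comp = cumsum(.data$start >= dplyr::lag(cummax(as.numeric(.data$end)), default = -Inf))) |>
    dplyr::group_by(.data$chrom, .data$comp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  mid <- reads$pos + floor(reads$length / 2)
  inside <- logical(nrow(reads))
  for (cn in unique(reads$chrom)) {
    p <- merged[merged$chrom == cn, ]
    r <- which(reads$chrom == cn)
    if (!nrow(p)) next
    idx <- findInterval(mid[r], p$start)
    inside[r] <- idx > 0 & mid[r] < p$end[pmax(idx, 1)]
  }
  mean(inside)
}

#' Annotate peaks with a genomic feature label
#'
#' Classifies each peak by its midpoint with priority
#' promoter > downstream > exon > intron > intergenic: *promoter* means
#' within `promoter_halfwidth` of a TSS (transcript start on the gene
#' strand), *downstream* within `downstream_extent` past the transcript
#' end on the gene strand, *exon*/*intron* by containment in the
#' transcript body.
#'
#' @param peaks Peak tibble.
#' @param gene_models Gene-model tibble from [read_gene_models()].
#' @param promoter_halfwidth Promoter half-width in bp around the TSS.
#' @param downstream_extent Downstream window in bp past the transcript
#'   end (default 5000).
#' @return `peaks` with an added `feature` column.
#' @export
annotate_feature <- function(peaks, gene_models, promoter_halfwidth = 1000,
                             downstream_extent = 5000) {
  check_intervals(peaks)
  mid <- floor((peaks$start + peaks$end) / 2)
  feature <- vapply(seq_len(nrow(peaks)), function(i) {
    gm <- gene_models[gene_models$chrom == peaks$chrom[i], ]
    if (!nrow(gm)) return("intergenic")
    m <- mid[i]
    tss <- ifelse(gm$strand == "+", gm$tx_start, gm$tx_end - 1)
    if (any(abs(m - tss) <= promoter_halfwidth)) return("promoter")
    down <- ifelse(gm$strand == "+",
                   m >= gm$tx_end & m < gm$tx_end + downstream_extent,
                   m < gm$tx_start & m >= gm$tx_start - downstream_extent)
    if (any(down)) return("downstream")
    in_tx <- m >= gm$tx_start & m < gm$tx_end
    if (any(in_tx)) {
      in_exon <- vapply(which(in_tx), function(j) {
        any(m >= gm$exon_starts[[j]] & m < gm$exon_ends[[j]])
      }, logical(1))
      return(if (any(in_exon)) "exon" else "intron")
    }
    "intergenic"
  }, character(1))
  dplyr::mutate(peaks, feature = feature)
}
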