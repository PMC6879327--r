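#' Genome objects
#'
#' A `genome` is a light container holding uppercase chromosome sequences
#' over the alphabet `A`, `C`, `G`, `T`, `N` together with their lengths.
#' All coordinates in quadchip are 0-based half-open (BED convention).
#'
#' @param sequences Named character vector of DNA sequences, one per
#'   chromosome. Lowercase is folded to uppercase.
#' @return An object of class `genome` with elements `sequences` (named
#'   character vector) and `sizes` (named numeric vector of lengths in bp).
#' @examples
#' g <- genome(c(chr1 = "acgtACGT", chr2 = "GGGTTAGGG"))
#' g$sizes
#' @export
genome <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == "") ||
      anyDuplicated(names(sequences))) {
    abort("sequences must have unique, non-empty chromosome names")
  }
  sequences <- toupper(sequences)
  bad <- stringr::str_locate(sequences, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf(
      "invalid character %s in sequence '%s' at position %d (1-based)",
      substr(sequences[i], bad[i], bad[i]), names(sequences)[i], bad[i]
    ))
  }
  structure(
    list(sequences = sequences, sizes = setNames(nchar(sequences), names(sequences))),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d chromosome(s), %s bp total\n",
              length(x$sequences), format(sum(x$sizes), big.mark = ",")))
  invisible(x)
}

#' Read a multi-record FASTA file into a genome
#'
#' Record names are taken up to the first whitespace; duplicate names and
#' non-IUPAC characters (anything outside `A/C/G/T/N` after case folding)
#' are errors.
#'
#' @param path Path to a FASTA file.
#' @return A [genome()] object; record order is preserved.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate FASTA record name: '%s'", nm[duplicated(nm)][1]))
  }
  genome(setNames(as.character(set), nm))
}

#' Write a genome to FASTA
#'
#' @param genome A [genome()] object.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(genome$sequences)) {
    s <- genome$sequences[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(c(paste0(">", nm), substring(s, starts, pmin(starts + width - 1, nchar(s)))), con)
  }
  invisible(path)
}

#' Read a chrom.sizes table
#'
#' @param path Two-column tab-separated file: chromosome name, length (bp).
#' @return A tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "size"),
                  col_types = readr::cols(chrom = "c", size = "d"),
                  progress = FALSE)
}

# Coerce the accepted size representations (tibble chrom/size, named
# vector, or genome) to a named numeric vector.
sizes_vec <- function(sizes) {
  if (inherits(sizes, "genome")) return(sizes$sizes)
  if (is.data.frame(sizes)) return(setNames(sizes$size, sizes$chrom))
  if (is.numeric(sizes) && !is.null(names(sizes))) return(sizes)
  abort("sizes must be a genome, a chrom/size tibble, or a named numeric vector")
}

#' Read a BED file of peaks
#'
#' Columns beyond the mandatory `chrom`, `start`, `end` are the optional
#' BED `name` and `score`; an irreproducible discovery rate (IDR) value can
#' be picked up from any extra numeric column by index. Coordinates are kept
#' verbatim in their 0-based half-open form.
#'
#' @param path Path to a BED file (>= 3 tab-separated columns, no header).
#' @param sizes Optional chromosome sizes (tibble, named vector or
#'   [genome()]); when supplied, intervals beyond a chromosome end are
#'   errors.
#' @param idr_col Optional 1-based column index holding an IDR value in
#'   `[0, 1]`.
#' @return A tibble of peaks with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `idr` (the last three `NA` when absent), in file order.
#' @export
read_bed <- function(path, sizes = NULL, idr_col = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 3) abort("BED file needs at least 3 tab-separated columns")
  peaks <- tibble(
    chrom = raw[[1]],
    start = as.numeric(raw[[2]]),
    end   = as.numeric(raw[[3]]),
    name  = if (ncol(raw) >= 4) raw[[4]] else NA_character_,
    score = if (ncol(raw) >= 5) suppressWarnings(as.numeric(raw[[5]])) else NA_real_,
    idr   = if (!is.null(idr_col)) as.numeric(raw[[idr_col]]) else NA_real_
  )
  bad <- which(!(peaks$start >= 0 & peaks$start < peaks$end))
  if (length(bad)) {
    abort(sprintf("invalid interval at line %d: start %s, end %s",
                  bad[1], format(peaks$start[bad[1]]), format(peaks$end[bad[1]])))
  }
  if (any(!is.na(peaks$idr)) && any(peaks$idr < 0 | peaks$idr > 1, na.rm = TRUE)) {
    abort("IDR values must lie in [0, 1]")
  }
  if (!is.null(sizes)) {
    sz <- sizes_vec(sizes)
    unknown <- setdiff(unique(peaks$chrom), names(sz))
    if (length(unknown)) abort(sprintf("chromosome '%s' absent from size table", unknown[1]))
    over <- which(peaks$end > sz[peaks$chrom])
    if (length(over)) {
      abort(sprintf("interval at line %d exceeds chromosome '%s' length %s",
                    over[1], peaks$chrom[over[1]], format(sz[[peaks$chrom[over[1]]]])))
    }
  }
  peaks
}

#' Write peaks as BED
#'
#' Emits BED3 when neither names nor scores are present, otherwise BED
#' with `name` (placeholder `.`) and `score` columns; coordinates are
#' written verbatim so that `write_bed(read_bed(f))` round-trips.
#'
#' @param peaks A peak tibble (`chrom`, `start`, `end`, optionally `name`,
#'   `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  cols <- list(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
               format(peaks$end, scientific = FALSE, trim = TRUE))
  has_name <- "name" %in% names(peaks) && any(!is.na(peaks$name))
  has_score <- "score" %in% names(peaks) && any(!is.na(peaks$score))
  if (has_name || has_score) {
    cols <- c(cols, list(dplyr::coalesce(as.character(peaks$name), ".")))
  }
  if (has_score) {
    cols <- c(cols, list(format(dplyr::coalesce(peaks$score, 0), scientific = FALSE, trim = TRUE)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a TSS table
#'
#' @param path Tab-separated file with header columns `gene`, `chrom`,
#'   `pos` (0-based TSS coordinate) and `strand` (`+`/`-`).
#' @return A tibble with those columns.
#' @export
read_tss_table <- function(path) {
  tss <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", chrom = "c", pos = "d", strand = "c"), progress = FALSE)
  if (any(!tss$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(tss$pos < 0)) abort("TSS positions must be >= 0")
  tss
}

#' Read a gene-model table
#'
#' The refFlat-style format carries one transcript per row with
#' comma-separated exon starts and ends.
#'
#' @param path Tab-separated file with header columns `gene`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `exon_starts`, `exon_ends`
#'   (comma-separated, 0-based half-open).
#' @return A tibble with list-columns `exon_starts`/`exon_ends` (numeric
#'   vectors, sorted and disjoint).
#' @export
read_gene_models <- function(path) {
  gm <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", chrom = "c", strand = "c", tx_start = "d", tx_end = "d",
    exon_starts = "c", exon_ends = "c"), progress = FALSE)
  parse_csv <- function(x) lapply(strsplit(x, ","), function(v) as.numeric(v[v != ""]))
  gm$exon_starts <- parse_csv(gm$exon_starts)
  gm$exon_ends <- parse_csv(gm$exon_ends)
  for (i in seq_len(nrow(gm))) {
    es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
    if (length(es) != length(ee) || any(ee <= es) ||
        any(es < gm$tx_start[i]) || any(ee > gm$tx_end[i]) ||
        is.unsorted(es, strictly = TRUE) || any(head(ee, -1) > tail(es, -1))) {
      abort(sprintf("gene '%s': exons must be sorted, disjoint and within the transcript span",
                    gm$gene[i]))
    }
  }
  gm
}

#' Distance from an interval to a point
#'
#' Distance is measured to the nearest *contained* base: 0 when the point
#' lies inside the half-open interval, otherwise the gap to `start` or to
#' `end - 1` (the last contained base). All arguments recycle.
#'
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @param pos 0-based point position on the same chromosome.
#' @param chrom,pos_chrom Optional chromosome names of the interval and the
#'   point; when both are given they must match.
#' @return Numeric distance(s) in bp.
#' @examples
#' interval_distance(100, 200, 250) # 51: measured to base 199
#' @export
interval_distance <- function(start, end, pos, chrom = NULL, pos_chrom = NULL) {
  if (any(start < 0) || any(start >= end)) abort("need 0 <= start < end")
  if (!is.null(chrom) && !is.null(pos_chrom) && any(chrom != pos_chrom)) {
    abort("interval and point are on different chromosomes")
  }
  inside <- pos >= start & pos < end
  ifelse(inside, 0, pmin(abs(pos - start), abs(pos - (end - 1))))
}

# Internal: validate a peak-like tibble has chrom/start/end with
# well-formed half-open intervals.
check_intervals <- function(x, what = "peaks") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    abort(sprintf("%s must have columns %s", what, paste(need, collapse = ", ")))
  }
  if (nrow(x) && (any(x$start < 0) || any(x$start >= x$end))) {
    abort(sprintf("%s contain an invalid interval (need 0 <= start < end)", what))
  }
  invisible(x)
}
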