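#' Define a potential G-quadruplex (PG4) pattern
#'
#' A PG4 pattern is `n_runs` G-tracts of at least `run_len` guanines
#' separated by loops of `loop_min` to `loop_max` bases. The widely used
#' default, four tracts of three guanines with loops of 1-7 bases, is the
#' quadparser convention; relaxing `loop_max` to 12 or 15 admits
#' longer-looped conformations.
#'
#' @param run_len Minimum guanines per tract (>= 2).
#' @param n_runs Number of tracts (>= 4).
#' @param loop_min,loop_max Loop length bounds in bp (`1 <= loop_min <=
#'   loop_max`); zero-length loops are rejected.
#' @param name Optional label; defaults to the `G<g>L<min>-<max>` scheme.
#' @return An object of class `g4_pattern`.
#' @examples
#' g4_pattern(loop_max = 15)
#' g4_preset("G3L1-7")
#' @export
g4_pattern <- function(run_len = 3, n_runs = 4, loop_min = 1, loop_max = 7,
                       name = NULL) {
  if (run_len < 2) abort("run_len must be >= 2")
  if (n_runs < 4) abort("n_runs must be >= 4")
  if (loop_min < 1 || loop_min > loop_max) abort("need 1 <= loop_min <= loop_max")
  structure(
    list(run_len = run_len, n_runs = n_runs,
         loop_min = loop_min, loop_max = loop_max,
         name = name %||% sprintf("G%dL%d-%d", run_len, loop_min, loop_max)),
    class = "g4_pattern"
  )
}

#' @export
print.g4_pattern <- function(x, ...) {
  cat(sprintf("<g4_pattern> %s: %d tracts of >=%d G, loops %d-%d bp\n",
              x$name, x$n_runs, x$run_len, x$loop_min, x$loop_max))
  invisible(x)
}

#' @rdname g4_pattern
#' @param preset One of `"G3L1-7"`, `"G3L1-12"`, `"G3L1-15"`.
#' @export
g4_preset <- function(preset = c("G3L1-7", "G3L1-12", "G3L1-15")) {
  preset <- match.arg(preset)
  loop_max <- as.numeric(sub("^G3L1-", "", preset))
  g4_pattern(run_len = 3, n_runs = 4, loop_min = 1, loop_max = loop_max)
}

#' Reverse complement of a DNA string
#'
#' @param seq A DNA string over `A/C/G/T/N`.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANTGCAN", seq))
}

# Maximal G-runs of length >= run_len as a start/end (1-based inclusive)
# data frame. Maximality means runs cannot be extended by adjacent G, so
# excess guanines belong to the tract, never to a loop.
g_runs <- function(seq, run_len) {
  m <- gregexpr(sprintf("G{%d,}", run_len), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(start = integer(), end = integer()))
  s <- as.integer(m)
  list(start = s, end = s + attr(m, "match.length") - 1L)
}

scan_pg4_one_strand <- function(seq, pattern) {
  runs <- g_runs(seq, pattern$run_len)
  k <- pattern$n_runs
  n <- length(runs$start)
  hits_start <- integer(); hits_end <- integer()
  if (n >= k) {
    # loop between consecutive qualifying tracts: length and N-freedom
    gap_len <- runs$start[-1] - runs$end[-n] - 1L
    gap_ok <- gap_len >= pattern$loop_min & gap_len <= pattern$loop_max
    if (any(gap_ok) && grepl("N", seq, fixed = TRUE)) {
      check <- which(gap_ok)
      has_n <- vapply(check, function(i) {
        grepl("N", substr(seq, runs$end[i] + 1L, runs$start[i + 1L] - 1L), fixed = TRUE)
      }, logical(1))
      gap_ok[check] <- !has_n
    }
    i <- 1L
    while (i + k - 1L <= n) {
      if (all(gap_ok[i:(i + k - 2L)])) {
        hits_start <- c(hits_start, runs$start[i])
        hits_end <- c(hits_end, runs$end[i + k - 1L])
        i <- i + k # scanning resumes after the accepted hit
      } else {
        i <- i + 1L
      }
    }
  }
  list(start = hits_start, end = hits_end, n = length(hits_start))
}

# Fast per-region motif count and union coverage (bases under any hit,
# both strands pooled), avoiding per-region tibble construction.
pg4_region_stats <- function(seqs, pattern, strand_mode = "both") {
  count <- integer(length(seqs)); covered <- numeric(length(seqs))
  do_plus <- strand_mode %in% c("both", "plus")
  do_minus <- strand_mode %in% c("both", "minus")
  for (i in seq_along(seqs)) {
    s <- integer(); e <- integer()
    if (do_plus) {
      h <- scan_pg4_one_strand(seqs[[i]], pattern)
      s <- h$start; e <- h$end
    }
    if (do_minus) {
      L <- nchar(seqs[[i]])
      h <- scan_pg4_one_strand(revcomp(seqs[[i]]), pattern)
      s <- c(s, L - h$end + 1L); e <- c(e, L - h$start + 1L)
    }
    count[i] <- length(s)
    if (length(s)) {
      o <- order(s)
      s <- s[o]; e <- e[o]
      # sweep-merge overlapping hit intervals, then sum merged lengths
      top <- cummax(c(0L, head(e, -1)))
      covered[i] <- sum(pmax(0L, e - pmax(s - 1L, top)))
    }
  }
  list(count = count, covered = covered)
}

#' Scan a sequence for nonoverlapping PG4 motifs
#'
#' Matching is leftmost and lazy: a hit begins at the earliest qualifying
#' G-tract, chains the nearest following tracts whose intervening loops
#' satisfy the length bounds, and ends at the last guanine of the final
#' tract; scanning then resumes at the next base, so hits on a strand never
#' overlap. The minus strand is scanned on the reverse complement and hits
#' are reported in plus-strand coordinates with the matched sequence in
#' plus-strand orientation. `N` never matches, neither in tracts nor in
#' loops.
#'
#' @param seq A DNA string over `A/C/G/T/N`.
#' @param pattern A [g4_pattern()].
#' @param strand_mode `"plus"`, `"minus"` or `"both"`.
#' @return A tibble of motif hits with columns `start`, `end` (0-based
#'   half-open, plus-strand), `strand` and `sequence`, sorted by start
#'   within each strand.
#' @examples
#' scan_pg4("GGGTTAGGGTTAGGGTTAGGG", g4_preset("G3L1-7"))
#' @export
scan_pg4 <- function(seq, pattern, strand_mode = c("both", "plus", "minus")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(pattern, "g4_pattern"))
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad != -1) {
    abort(sprintf("invalid character '%s' at position %d", substr(seq, bad, bad), bad))
  }
  out <- list()
  if (strand_mode %in% c("both", "plus")) {
    h <- scan_pg4_one_strand(seq, pattern)
    out$plus <- if (h$n) {
      tibble(start = h$start - 1, end = as.numeric(h$end), strand = "+",
             sequence = substring(seq, h$start, h$end))
    } else {
      tibble(start = numeric(), end = numeric(),
             strand = character(), sequence = character())
    }
  }
  if (strand_mode %in% c("both", "minus")) {
    L <- nchar(seq)
    h <- scan_pg4_one_strand(revcomp(seq), pattern)
    if (h$n) {
      # reflect reverse-complement coordinates back to the plus strand
      start <- L - h$end
      end <- L - h$start + 1
      ord <- order(start)
      out$minus <- tibble(
        start = start[ord], end = end[ord], strand = "-",
        sequence = substring(seq, start[ord] + 1, end[ord])
      )
    } else {
      out$minus <- tibble(start = numeric(), end = numeric(),
                          strand = character(), sequence = character())
    }
  }
  dplyr::bind_rows(out)
}

#' Count nonoverlapping PG4 motifs in a sequence
#'
#' @inheritParams scan_pg4
#' @return Integer count (plus- and minus-strand hits summed under
#'   `strand_mode = "both"`).
#' @export
count_pg4 <- function(seq, pattern, strand_mode = c("both", "plus", "minus")) {
  nrow(scan_pg4(seq, pattern, strand_mode))
}

#' Classify a read as telomeric
#'
#' A read is telomeric when it contains `min_units` tandem copies of the
#' telomeric repeat on either strand, i.e. `TTAGGG` x `min_units` or its
#' reverse complement `CCCTAA` x `min_units` as a substring.
#'
#' @param seq Character vector of read sequences.
#' @param min_units Required number of tandem repeat units (default 2).
#' @return Logical vector.
#' @examples
#' is_telomeric_read("AATTAGGGTTAGGGCA")
#' @export
is_telomeric_read <- function(seq, min_units = 2) {
  if (min_units < 1) abort("min_units must be >= 1")
  seq <- toupper(seq)
  stringr::str_detect(seq, stringr::fixed(strrep("TTAGGG", min_units))) |
    stringr::str_detect(seq, stringr::fixed(strrep("CCCTAA", min_units)))
}

#' Locate telomeric repeat units on the plus strand
#'
#' Finds every (possibly overlapping) occurrence of the 6-mer `TTAGGG`.
#'
#' @param seq A DNA string.
#' @return Ascending 0-based start offsets (numeric vector, possibly
#'   empty).
#' @examples
#' find_telomeric_tracts("TTAGGGTTAGGG")
#' @export
find_telomeric_tracts <- function(seq) {
  m <- gregexpr("(?=TTAGGG)", toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) return(numeric(0))
  as.numeric(m) - 1
}

#' Extract region sequences from a genome
#'
#' @param genome A [genome()] object.
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Character vector of plus-strand sequences, one per region.
#' @export
region_sequence <- function(genome, regions) {
  check_intervals(regions, "regions")
  unknown <- setdiff(unique(regions$chrom), names(genome$sizes))
  if (length(unknown)) abort(sprintf("chromosome '%s' not in genome", unknown[1]))
  if (nrow(regions) && any(regions$end > genome$sizes[regions$chrom])) {
    abort("region extends beyond chromosome end")
  }
  substring(genome$sequences[regions$chrom], regions$start + 1, regions$end)
}
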