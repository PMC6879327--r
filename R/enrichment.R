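#' Sample length-matched random control regions
#'
#' For each peak, draws `n_per_peak` random regions of exactly that peak's
#' length from across the genome: the chromosome is chosen with
#' probability proportional to its length and the start uniformly among
#' the positions where the region fits. Draws overlapping any exclusion
#' interval (by default the peaks themselves) or containing more than
#' `max_n_frac` ambiguous `N` bases are rejected and redrawn.
#'
#' @param peaks Peak tibble.
#' @param sizes Chromosome sizes (tibble, named vector or [genome()]).
#' @param n_per_peak Control regions per peak (default 100).
#' @param seed Integer seed making the draw deterministic.
#' @param exclusions Interval tibble never to be overlapped; defaults to
#'   `peaks`.
#' @param genome Optional [genome()] enabling the `N`-content filter.
#' @param max_n_frac Maximum tolerated fraction of `N` (default 0.1).
#' @param max_draws Rejection budget per region (default 1000).
#' @return Tibble of control regions (`chrom`, `start`, `end`,
#'   `peak_index`).
#' @export
sample_control_regions <- function(peaks, sizes, n_per_peak = 100, seed = NULL,
                                   exclusions = peaks, genome = NULL,
                                   max_n_frac = 0.1, max_draws = 1000) {
  check_intervals(peaks)
  sz <- sizes_vec(sizes)
  lens <- peaks$end - peaks$start
  if (any(lens >= max(sz))) abort("every peak must be shorter than the longest chromosome")
  draw_all <- function() {
    out <- vector("list", nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      L <- lens[i]
      fit <- sz[sz >= L]
      got_chrom <- character(n_per_peak); got_start <- numeric(n_per_peak)
      for (j in seq_len(n_per_peak)) {
        ok <- FALSE
        for (try in seq_len(max_draws)) {
          cn <- sample(names(fit), 1, prob = fit)
          s <- sample.int(fit[[cn]] - L + 1, 1) - 1
          e <- s + L
          hit_excl <- nrow(exclusions) > 0 &&
            any(exclusions$chrom == cn & exclusions$start < e & s < exclusions$end)
          if (hit_excl) next
          if (!is.null(genome)) {
            sq <- substring(genome$sequences[[cn]], s + 1, e)
            if (stringr::str_count(sq, stringr::fixed("N")) > max_n_frac * L) next
          }
          got_chrom[j] <- cn; got_start[j] <- s
          ok <- TRUE
          break
        }
        if (!ok) {
          abort(sprintf("rejection budget exhausted for peak %d (length %d)", i, L))
        }
      }
      out[[i]] <- tibble(chrom = got_chrom, start = got_start,
                         end = got_start + L, peak_index = i)
    }
    dplyr::bind_rows(out)
  }
  if (!is.null(seed)) withr::with_seed(seed, draw_all()) else draw_all()
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value as the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the probability of the observed table (with a relative tolerance
#' of 1e-7 on the comparison).
#'
#' @param table A 2x2 matrix of non-negative counts, or the four counts
#'   `a, b, c, d` in row-major order.
#' @return The two-sided p-value in `(0, 1]`. A degenerate margin (an
#'   all-zero row or column) yields `p = 1` with a warning.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4 || any(x < 0) || any(x != floor(x))) {
    abort("need four non-negative integer counts")
  }
  if (is.matrix(table)) {
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warn("degenerate margin: returning p = 1 (no evidence)")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Odds ratio (a d)/(b c) with a 0.5 continuity correction when any cell
# is zero.
odds_ratio_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

new_g4_enrichment <- function(kind, pattern, a, b, c, d, n_controls_per_peak,
                              seed, n_peaks, n_controls) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("peaks", "controls"),
                                c("with", "without")))
  structure(
    list(kind = kind, pattern = pattern$name, table = tab,
         odds_ratio = odds_ratio_2x2(a, b, c, d),
         p_value = fisher_exact_2x2(tab),
         n_controls_per_peak = n_controls_per_peak, seed = seed,
         n_peaks = n_peaks, n_controls = n_controls),
    class = "g4_enrichment"
  )
}

#' @export
print.g4_enrichment <- function(x, ...) {
  cat(sprintf("<g4_enrichment: %s> pattern %s\n", x$kind, x$pattern))
  print(x$table)
  cat(sprintf("odds ratio %.3g, two-sided Fisher p = %.3g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' @export
tidy.g4_enrichment <- function(x, ...) {
  tibble(
    group = rep(rownames(x$table), each = 2),
    property = rep(colnames(x$table), 2),
    count = as.numeric(t(x$table))
  )
}

#' @export
glance.g4_enrichment <- function(x, ...) {
  tibble(kind = x$kind, pattern = x$pattern, odds_ratio = x$odds_ratio,
         p_value = x$p_value, n_peaks = x$n_peaks, n_controls = x$n_controls,
         n_controls_per_peak = x$n_controls_per_peak,
         seed = x$seed %||% NA_integer_)
}

#' PG4 motif-count enrichment in peaks versus controls
#'
#' Builds the 2x2 table contrasting the total number of nonoverlapping
#' PG4 motifs against the number of bases not covered by any motif, in
#' the observed peaks (row 1) versus the pooled length-matched controls
#' (row 2), and tests it with [fisher_exact_2x2()].
#'
#' @param peaks Peak tibble (non-empty).
#' @param controls Control-region tibble from [sample_control_regions()].
#' @param genome A [genome()].
#' @param pattern A [g4_pattern()].
#' @param strand_mode Strands scanned (default `"both"`).
#' @param seed Seed recorded in the report (the one used for the
#'   controls).
#' @return A `g4_enrichment` object; see [tidy()] and [glance()].
#' @export
motif_count_enrichment <- function(peaks, controls, genome, pattern,
                                   strand_mode = "both", seed = NULL) {
  if (!nrow(peaks)) abort("empty peak set")
  stat <- function(regions) {
    seqs <- region_sequence(genome, regions)
    # union coverage so plus/minus overlaps are not double-counted
    st <- pg4_region_stats(seqs, pattern, strand_mode)
    c(motifs = sum(st$count),
      uncovered = sum(regions$end - regions$start) - sum(st$covered))
  }
  s_pk <- stat(peaks); s_ct <- stat(controls)
  n_per <- if (nrow(controls)) nrow(controls) / nrow(peaks) else 0
  new_g4_enrichment("motif-count", pattern,
                    s_pk[["motifs"]], s_pk[["uncovered"]],
                    s_ct[["motifs"]], s_ct[["uncovered"]],
                    n_per, seed, nrow(peaks), nrow(controls))
}

#' PG4 presence enrichment in peaks versus controls
#'
#' The converse test: row 1 counts peaks with at least one PG4 hit versus
#' peaks with none; row 2 the same over the pooled controls.
#'
#' @inheritParams motif_count_enrichment
#' @return A `g4_enrichment` object.
#' @export
peak_presence_enrichment <- function(peaks, controls, genome, pattern,
                                     strand_mode = "both", seed = NULL) {
  if (!nrow(peaks)) abort("empty peak set")
  present <- function(regions) {
    seqs <- region_sequence(genome, regions)
    pg4_region_stats(seqs, pattern, strand_mode)$count > 0
  }
  pk <- present(peaks); ct <- present(controls)
  n_per <- if (nrow(controls)) nrow(controls) / nrow(peaks) else 0
  new_g4_enrichment("peak-presence", pattern,
                    sum(pk), sum(!pk), sum(ct), sum(!ct),
                    n_per, seed, nrow(peaks), nrow(controls))
}

#' Bin a genome and count ChIP and input reads per bin
#'
#' Reads are assigned to the bin containing their midpoint.
#'
#' @param chip,input Read placement tibbles (`chrom`, `pos`, `length`).
#' @param sizes Chromosome sizes.
#' @param bin_size Bin width in bp (default 50).
#' @return A tibble with columns `chrom`, `bin_start`, `chip`, `input`
#'   covering every bin of every chromosome.
#' @export
bin_track <- function(chip, input, sizes, bin_size = 50) {
  sz <- sizes_vec(sizes)
  grid <- purrr::map_dfr(names(sz), function(cn) {
    tibble(chrom = cn, bin_start = seq(0, sz[[cn]] - 1, by = bin_size))
  })
  count_by_bin <- function(reads, col) {
    mid <- reads$pos + floor(reads$length / 2)
    tibble(chrom = reads$chrom, bin_start = floor(mid / bin_size) * bin_size) |>
      dplyr::count(.data$chrom, .data$bin_start, name = col)
  }
  grid |>
    dplyr::left_join(count_by_bin(chip, "chip"), by = c("chrom", "bin_start")) |>
    dplyr::left_join(count_by_bin(input, "input"), by = c("chrom", "bin_start")) |>
    dplyr::mutate(chip = dplyr::coalesce(.data$chip, 0L),
                  input = dplyr::coalesce(.data$input, 0L))
}

#' Bin-level ChIP-versus-input enrichment
#'
#' Tests each bin's ChIP count against a one-sided binomial null whose
#' success probability is the bin's share of the input signal with a +1
#' pseudo-count, `p0 = (input_bin + 1) / (input_total + n_bins)`, and
#' controls the FDR across bins by Benjamini-Hochberg.
#'
#' @param bins A bin table from [bin_track()].
#' @param fdr FDR level (default 0.05).
#' @return An object of class `bin_enrichment`; `tidy()` returns the
#'   per-bin table with `p_value` and `significant`, `glance()` the
#'   significant fraction.
#' @export
bin_enrichment <- function(bins, fdr = 0.05) {
  if (!nrow(bins)) abort("zero bins")
  chip_total <- sum(bins$chip); input_total <- sum(bins$input)
  if (chip_total == 0 || input_total == 0) abort("ChIP and input totals must be > 0")
  p0 <- (bins$input + 1) / (input_total + nrow(bins))
  p <- pbinom(bins$chip - 1, chip_total, p0, lower.tail = FALSE)
  sig <- bh_fdr(p, fdr)
  structure(
    list(bins = dplyr::mutate(bins, p_value = p, significant = sig),
         fdr = fdr, significant_fraction = mean(sig)),
    class = "bin_enrichment"
  )
}

#' @export
print.bin_enrichment <- function(x, ...) {
  cat(sprintf("<bin_enrichment> %d bins, %.3g%% significant at FDR %g\n",
              nrow(x$bins), 100 * x$significant_fraction, x$fdr))
  invisible(x)
}

#' @export
tidy.bin_enrichment <- function(x, ...) x$bins

#' @export
glance.bin_enrichment <- function(x, ...) {
  tibble(n_bins = nrow(x$bins), fdr = x$fdr,
         n_significant = sum(x$bins$significant),
         significant_fraction = x$significant_fraction)
}

#' Benjamini-Hochberg rejection flags
#'
#' Standard step-up rule: reject the `k` smallest p-values where `k` is
#' the largest rank with `p_(k) <= k * alpha / m`.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return Logical rejection flags aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH") <= alpha
}
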