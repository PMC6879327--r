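# Independent brute-force oracles used to cross-check the package's
# algorithmic code paths. These deliberately take the slow, literal
# route: enumerate, test a predicate, pick greedily.

# Does `sub`, cut out of `seq` at [s, e] (1-based inclusive), match the
# PG4 grammar exactly: it decomposes into n_runs maximal G-tracts of
# >= run_len separated by N-free loops within the length bounds, begins
# at the first tract and ends at the last, and is flank-maximal in `seq`?
oracle_is_match <- function(chars, s, e, pattern) {
  L <- length(chars)
  if (s > 1 && chars[s - 1] == "G") return(FALSE)
  if (e < L && chars[e + 1] == "G") return(FALSE)
  sub <- chars[s:e]
  if (sub[1] != "G" || sub[length(sub)] != "G") return(FALSE)
  r <- rle(sub)
  qual <- which(r$values == "G" & r$lengths >= pattern$run_len)
  if (length(qual) != pattern$n_runs) return(FALSE)
  if (qual[1] != 1 || qual[length(qual)] != length(r$values)) return(FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in seq_len(length(qual) - 1)) {
    gap <- starts[qual[j + 1]] - ends[qual[j]] - 1
    if (gap < pattern$loop_min || gap > pattern$loop_max) return(FALSE)
    if (any(sub[(ends[qual[j]] + 1):(starts[qual[j + 1]] - 1)] == "N")) return(FALSE)
  }
  if (any(sub[unlist(mapply(function(a, b) a:b, starts[qual], ends[qual]))] == "N")) return(FALSE)
  TRUE
}

# Plus-strand brute force: for every candidate start, find the minimal
# matching end; then accept matches greedily left to right without
# overlap. Returns 0-based half-open coordinates.
oracle_scan_plus <- function(seq, pattern) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  max_run <- max(c(0, rle(chars)$lengths[rle(chars)$values == "G"]))
  span <- pattern$n_runs * max(max_run, pattern$run_len) +
    (pattern$n_runs - 1) * pattern$loop_max
  min_span <- pattern$n_runs * pattern$run_len + (pattern$n_runs - 1) * pattern$loop_min
  cand_start <- integer(); cand_end <- integer()
  for (s in seq_len(L)) {
    if (chars[s] != "G" || (s > 1 && chars[s - 1] == "G")) next
    if (s + min_span - 1 > L) next
    # a match must open with a qualifying tract
    if (any(chars[s:(s + pattern$run_len - 1)] != "G")) next
    for (e in (s + min_span - 1):min(L, s + span - 1)) {
      if (e > L) break
      if (oracle_is_match(chars, s, e, pattern)) {
        cand_start <- c(cand_start, s); cand_end <- c(cand_end, e)
        break # lazy: minimal end for this start
      }
    }
  }
  keep_s <- integer(); keep_e <- integer()
  cursor <- 0
  for (i in seq_along(cand_start)) {
    if (cand_start[i] > cursor) {
      keep_s <- c(keep_s, cand_start[i]); keep_e <- c(keep_e, cand_end[i])
      cursor <- cand_end[i]
    }
  }
  data.frame(start = keep_s - 1, end = keep_e)
}

oracle_scan_both <- function(seq, pattern) {
  plus <- oracle_scan_plus(seq, pattern)
  L <- nchar(seq)
  rc <- oracle_scan_plus(quadchip::revcomp(seq), pattern)
  minus <- data.frame(start = L - rc$end, end = L - rc$start)
  minus <- minus[order(minus$start), , drop = FALSE]
  list(plus = plus, minus = minus)
}

# Connected components of the interval-overlap graph by repeated
# expansion; emits min-start/max-end spans for components holding peaks
# from both replicates.
oracle_common_peaks <- function(rep1, rep2) {
  all <- rbind(
    data.frame(chrom = rep1$chrom, start = rep1$start, end = rep1$end, rep = 1),
    data.frame(chrom = rep2$chrom, start = rep2$start, end = rep2$end, rep = 2)
  )
  n <- nrow(all)
  if (!n) return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  overlaps <- function(i, j) {
    all$chrom[i] == all$chrom[j] && all$start[i] < all$end[j] && all$start[j] < all$end[i]
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && overlaps(i, j) && comp[j] != comp[i]) {
        old <- comp[c(i, j)]
        comp[comp %in% old] <- min(old)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(k) {
    m <- all[comp == k, ]
    if (length(unique(m$rep)) < 2) return(NULL)
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end))
  }))
  if (is.null(out)) return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Literal Benjamini-Hochberg step-up.
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Random DNA of length n with the given G weight (rest split over A/C/T).
random_dna <- function(n, g_prob = 0.25) {
  other <- (1 - g_prob) / 3
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(other, other, g_prob, other)), collapse = "")
}

random_peaks <- function(n, chroms = c("chrA", "chrB"), max_pos = 1000, max_len = 60) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}
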