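#' @export
autoplot.fid_fit <- function(object, ...) {
  d <- object$tod_curve
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$conc, y = .data$tod_reported)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$dc50, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "titrant (molar equivalents)", y = "TO displacement (%)",
                  title = sprintf("G4-FID titration (DC50 = %.3g eq)", object$dc50)) +
    ggplot2::theme_minimal()
  if (!is.na(object$kd_indicative)) {
    grid <- tibble(conc = seq(min(d$conc), max(d$conc), length.out = 200))
    grid$tod_reported <- 100 * grid$conc^object$hill_coef /
      (grid$conc^object$hill_coef + object$kd_indicative^object$hill_coef)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' @export
autoplot.g4_enrichment <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(rate = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$property == "with")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::labs(
      x = NULL, y = "rate with property",
      title = sprintf("%s enrichment, %s", object$kind, object$pattern),
      subtitle = sprintf("odds ratio %.3g, Fisher p = %.3g", object$odds_ratio, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bin_enrichment <- function(object, ...) {
  d <- object$bins
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_start, y = .data$chip)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant), width = attr(d, "bin_size") %||% 50) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "ChIP reads / bin",
                  title = sprintf("%.3g%% of bins enriched over input at FDR %g",
                                  100 * object$significant_fraction, object$fdr)) +
    ggplot2::theme_minimal()
}

#' Plot TSS proximity counts
#'
#' @param counts Output of [tss_proximity_counts()].
#' @return A ggplot.
#' @export
plot_tss_proximity <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$threshold / 1000), y = .data$n_peaks)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::labs(x = "distance to nearest TSS (kb)", y = "peaks") +
    ggplot2::theme_minimal()
}
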