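#' Percentage thiazole-orange displacement (TOD)
#'
#' The G4-FID readout: with `FA1` the fluorescence area recorded after
#' probe addition but before any titrant, the displacement at titration
#' point `x` is `TOD = 100 - (FAx / FA1) * 100`, so TOD is 0 at the
#' baseline and 100 at complete displacement.
#'
#' @param fa_x Fluorescence area(s) at the titration point(s)
#'   (arbitrary units, >= 0).
#' @param fa1 Baseline fluorescence area (> 0).
#' @return TOD in percent; may be negative for noisy areas above the
#'   baseline (clamp for reporting with `pmin(pmax(tod, 0), 100)`).
#' @export
tod_percent <- function(fa_x, fa1) {
  if (length(fa1) != 1 || fa1 <= 0) abort("fa1 must be a single positive area")
  if (any(fa_x < 0)) abort("fluorescence areas must be >= 0")
  100 - (fa_x / fa1) * 100
}

#' Build and validate a G4-FID titration series
#'
#' @param conc Titrant amounts in molar equivalents, non-negative and
#'   strictly increasing, starting at 0 (the probe-only baseline).
#' @param fa Fluorescence areas (arbitrary units); the first value is the
#'   baseline `FA1` and must be positive.
#' @return A tibble with columns `conc`, `fa` and `tod` (raw, unclamped).
#' @export
fid_series <- function(conc, fa) {
  if (length(conc) != length(fa)) abort("conc and fa must have the same length")
  if (length(conc) < 2) abort("a titration needs at least 2 points")
  if (conc[1] != 0) abort("the first titration point must be the conc = 0 baseline")
  if (any(diff(conc) <= 0) || any(conc < 0)) abort("concentrations must be non-negative and strictly increasing")
  if (fa[1] <= 0) abort("baseline fluorescence area FA1 must be > 0")
  tibble(conc = conc, fa = fa, tod = tod_percent(fa, fa[1]))
}

#' Read a G4-FID titration from TSV
#'
#' @param path Tab-separated file with header columns `conc` and
#'   `fluorescence_area`.
#' @return A [fid_series()] tibble.
#' @export
read_fid_series <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    conc = "d", fluorescence_area = "d"), progress = FALSE)
  fid_series(d$conc, d$fluorescence_area)
}

# Raw TOD values and an isotonic (monotone non-decreasing) smooth of them.
tod_smoothed <- function(series) {
  stopifnot(all(c("conc", "tod") %in% names(series)))
  list(raw = series$tod, smooth = isoreg(series$conc, series$tod)$yf)
}

#' DC50 of a G4-FID titration
#'
#' The titrant amount displacing 50% of the probe, obtained by linear
#' interpolation between the bracketing points of the monotone-smoothed
#' (isotonic) TOD curve. If the raw curve crosses 50% more than once the
#' first crossing is used and a warning is emitted.
#'
#' @param series A [fid_series()] tibble (or any tibble with `conc` and
#'   `tod`).
#' @return DC50 in the units of `conc`.
#' @examples
#' s <- fid_series(c(0, 1, 2, 4), c(100, 75, 50, 20))
#' dc50(s) # 2
#' @export
dc50 <- function(series) {
  ts <- tod_smoothed(series)
  y <- ts$smooth
  if (max(y) < 50) abort("DC50 not reached: maximum TOD below 50%")
  crossings <- sum(diff(ts$raw >= 50) != 0)
  if (crossings > 1) warn("TOD curve crosses 50% more than once; using the first crossing")
  i <- which(y >= 50)[1]
  if (i == 1) return(series$conc[1])
  y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return(series$conc[i])
  series$conc[i - 1] + (50 - y0) / (y1 - y0) * (series$conc[i] - series$conc[i - 1])
}

#' Hill fit of a G4-FID displacement curve
#'
#' Least-squares fit of `TOD(c) = 100 c^h / (c^h + K^h)` by
#' Levenberg-Marquardt, initialised at `K = ` the interpolated DC50 and
#' `h = 1`. `K` is the indicative dissociation-constant midpoint and `h`
#' the Hill coefficient. Raw (unclamped) TOD values are fitted.
#'
#' @param series A [fid_series()] tibble with at least 4 points.
#' @return A list with elements `kd_indicative`, `hill_coef` and `fit`
#'   (the underlying `nls` object).
#' @export
fit_hill <- function(series) {
  if (nrow(series) < 4) abort("Hill fit needs >= 4 titration points")
  k0 <- tryCatch(dc50(series), error = function(e) stats::median(series$conc[-1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      tod ~ 100 * conc^h / (conc^h + K^h),
      data = series,
      start = list(K = k0, h = 1),
      lower = c(K = 1e-9, h = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(sprintf("Hill fit did not converge: %s", conditionMessage(e)))
  )
  est <- coef(fit)
  list(kd_indicative = unname(est["K"]), hill_coef = unname(est["h"]), fit = fit)
}

#' Analyse a G4-FID titration
#'
#' Combines the TOD curve, the interpolated [dc50()] and, when enough
#' points are available, the indicative [fit_hill()] parameters into one
#' result object.
#'
#' @param series A [fid_series()] tibble.
#' @return An object of class `fid_fit` with elements `tod_curve` (with
#'   `tod_reported` clamped to `[0, 100]`), `dc50`, `kd_indicative` and
#'   `hill_coef` (the last two `NA` when the fit is unavailable).
#' @export
fid_analyze <- function(series) {
  d <- dc50(series)
  hill <- if (nrow(series) >= 4) {
    tryCatch(fit_hill(series), error = function(e) NULL)
  }
  structure(
    list(
      tod_curve = dplyr::mutate(series, tod_reported = pmin(pmax(.data$tod, 0), 100)),
      dc50 = d,
      kd_indicative = if (is.null(hill)) NA_real_ else hill$kd_indicative,
      hill_coef = if (is.null(hill)) NA_real_ else hill$hill_coef
    ),
    class = "fid_fit"
  )
}

#' @export
print.fid_fit <- function(x, ...) {
  cat(sprintf("<fid_fit> %d titration points; DC50 = %.4g eq; indicative Kd = %.4g, Hill h = %.3g\n",
              nrow(x$tod_curve), x$dc50, x$kd_indicative, x$hill_coef))
  invisible(x)
}

#' @export
tidy.fid_fit <- function(x, ...) x$tod_curve

#' @export
glance.fid_fit <- function(x, ...) {
  tibble(dc50 = x$dc50, kd_indicative = x$kd_indicative,
         hill_coef = x$hill_coef, n_points = nrow(x$tod_curve))
}
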