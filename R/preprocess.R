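#' Convert percent transmittance to absorbance
#'
#' Applies `A = 2 - log10(%T)`, the Beer-Lambert ordinate in which band
#' intensity is linear in analyte concentration.
#'
#' @param s An [ir_spectrum] in `percent_transmittance` mode with all values
#'   in (0, 100].
#' @return The spectrum in `absorbance` mode, grid unchanged.
#' @export
transmittance_to_absorbance <- function(s) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (s$mode != "percent_transmittance") {
    stop("spectrum is not in percent_transmittance mode", call. = FALSE)
  }
  check_ordinate_range(s$ordinate, s$mode)
  out <- s
  out$ordinate <- 2 - log10(s$ordinate)
  out$mode <- "absorbance"
  out
}

#' Convert absorbance back to percent transmittance
#'
#' Exact inverse of [transmittance_to_absorbance()]: `%T = 100 * 10^(-A)`.
#'
#' @param s An [ir_spectrum] in `absorbance` mode.
#' @return The spectrum in `percent_transmittance` mode.
#' @export
absorbance_to_transmittance <- function(s) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (s$mode != "absorbance") {
    stop("spectrum is not in absorbance mode", call. = FALSE)
  }
  out <- s
  out$ordinate <- 100 * 10^(-s$ordinate)
  out$mode <- "percent_transmittance"
  out
}

#' Kubelka-Munk transform of a diffuse-reflectance spectrum
#'
#' With `R = %R/100`, computes `f(R) = (1 - R)^2 / (2R)`, the remission
#' function that is approximately linear in analyte concentration for an
#' optically thick powder bed. `f` is strictly decreasing in `R` on (0, 1].
#'
#' @param s An [ir_spectrum] in `percent_reflectance` mode with all values in
#'   (0, 100]. Values of 0 or below are rejected, never clipped: an epsilon
#'   floor would manufacture signal.
#' @return The spectrum in `kubelka_munk` mode.
#' @export
reflectance_to_km <- function(s) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (s$mode != "percent_reflectance") {
    stop("spectrum is not in percent_reflectance mode", call. = FALSE)
  }
  check_ordinate_range(s$ordinate, s$mode)
  r <- s$ordinate / 100
  out <- s
  out$ordinate <- (1 - r)^2 / (2 * r)
  out$mode <- "kubelka_munk"
  out
}

#' Invert the Kubelka-Munk transform
#'
#' Solves `f = (1-R)^2/(2R)` for the physical root `R in (0, 1]`:
#' `R = 1 + f - sqrt(f^2 + 2f)`. Used by the simulator to synthesise
#' reflectance spectra from a KM-linear forward model.
#'
#' @param s An [ir_spectrum] in `kubelka_munk` mode with all values >= 0.
#' @return The spectrum in `percent_reflectance` mode (`100 * R`).
#' @export
km_to_reflectance <- function(s) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (s$mode != "kubelka_munk") {
    stop("spectrum is not in kubelka_munk mode", call. = FALSE)
  }
  f <- s$ordinate
  if (any(f < 0)) {
    stop("Kubelka-Munk values must be >= 0 for inversion", call. = FALSE)
  }
  out <- s
  out$ordinate <- 100 * (1 + f - sqrt(f^2 + 2 * f))
  out$mode <- "percent_reflectance"
  out
}

#' Two-point chord baseline correction over a window
#'
#' Subtracts the straight line through the window's two endpoint ordinates.
#' Each endpoint ordinate is the mean of the `m` nearest on-grid points
#' (default `m = 1`, i.e. the endpoints themselves), which damps the
#' influence of noise at the anchors. Endpoint residuals are exactly zero for
#' `m = 1`; any affine (linear-in-wavenumber) component of the signal is
#' removed exactly for every `m`.
#'
#' @param s An [ir_spectrum] in `absorbance` or `kubelka_munk` mode; it is
#'   sliced to `w` first.
#' @param w A [spectral_window].
#' @param m Number of grid points averaged at each window end (default 1).
#' @return The baseline-corrected sub-spectrum over `w`.
#' @export
chord_baseline <- function(s, w, m = 1L) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (!s$mode %in% c("absorbance", "kubelka_munk")) {
    stop("chord baseline operates on absorbance or kubelka_munk spectra", call. = FALSE)
  }
  sub <- slice_window(s, w)
  n <- length(sub$wavenumbers)
  m <- as.integer(m)
  if (m < 1L || 2L * m > n) {
    stop("endpoint smoothing width `m` must satisfy 1 <= m <= n/2", call. = FALSE)
  }
  x <- sub$wavenumbers
  y <- sub$ordinate
  x_lo <- mean(x[seq_len(m)]);            y_lo <- mean(y[seq_len(m)])
  x_hi <- mean(x[seq(n - m + 1L, n)]);    y_hi <- mean(y[seq(n - m + 1L, n)])
  slope <- (y_hi - y_lo) / (x_hi - x_lo)
  sub$ordinate <- y - (y_lo + slope * (x - x_lo))
  sub
}

#' Baseline-corrected band area over an integration window
#'
#' Applies the chord baseline over `w`, then integrates the residual by the
#' trapezoidal rule. The result is in ordinate units times cm^-1; vendor
#' software reports the same quantity in display units (e.g. mm^2), which
#' differ only by a fixed scale factor that all downstream calibration and
#' validation statistics are invariant to. Noise can drive the corrected
#' area slightly negative; only finiteness is guaranteed.
#'
#' @inheritParams chord_baseline
#' @return An object of class `band_area`: list with `value` (area),
#'   `window`, and `mode_used` (`"absorbance"` or `"kubelka_munk"`).
#' @examples
#' s <- ir_spectrum(0:4, c(0, 0, 2, 0, 0), "absorbance")
#' band_area(s, spectral_window(4, 0))$value # 2 by the trapezoidal rule
#' @export
band_area <- function(s, w, m = 1L) {
  corrected <- chord_baseline(s, w, m = m)
  x <- corrected$wavenumbers
  y <- corrected$ordinate
  value <- sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
  structure(list(value = value, window = w, mode_used = corrected$mode),
            class = "band_area")
}

#' @export
print.band_area <- function(x, ...) {
  cat(sprintf("<band_area> %.6g (%s, %.6g-%.6g cm-1)\n",
              x$value, x$mode_used, x$window$high, x$window$low))
  invisible(x)
}

#' Quantify a raw instrument spectrum to a band area
#'
#' The full spectrum-to-number chain for either measurement mode:
#' transmittance spectra are converted to absorbance and reflectance spectra
#' to the Kubelka-Munk function, then chord-baseline-corrected and
#' trapezoid-integrated over the analytical window. Spectra already in a
#' linear ordinate (absorbance / Kubelka-Munk) are integrated directly.
#'
#' @inheritParams chord_baseline
#' @param area_ordinate For transmittance input, `"absorbance"` (default)
#'   integrates the Beer-Lambert-linear ordinate `2 - log10(%T)`; `"raw"`
#'   integrates the transmittance deficit `100 - %T` without the log
#'   transform, for comparison with software that integrates the raw trace.
#'   Calibration is empirical in either case.
#' @return A `band_area`.
#' @export
quantify <- function(s, w, m = 1L, area_ordinate = c("absorbance", "raw")) {
  stopifnot(inherits(s, "ir_spectrum"))
  area_ordinate <- match.arg(area_ordinate)
  lin <- switch(s$mode,
    percent_transmittance = {
      if (area_ordinate == "raw") {
        out <- s
        out$ordinate <- 100 - s$ordinate # peak-up deficit, no log transform
        out$mode <- "absorbance"
        out
      } else {
        transmittance_to_absorbance(s)
      }
    },
    percent_reflectance = reflectance_to_km(s),
    absorbance = s,
    kubelka_munk = s
  )
  band_area(lin, w, m = m)
}
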