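#' Ordinate modes understood by the package
#'
#' Raw instrument ordinates are percent transmittance (KBr pellet) or percent
#' reflectance (DRIFTS); quantification happens in absorbance or Kubelka-Munk
#' units, both of which are linear in analyte concentration.
#'
#' @format A character vector of the four recognised mode names.
#' @export
ordinate_modes <- c(
  "percent_transmittance", "percent_reflectance",
  "absorbance", "kubelka_munk"
)

#' Construct a mid-infrared spectrum
#'
#' A spectrum is a wavenumber grid (cm^-1) with one ordinate value per grid
#' point and an explicit ordinate mode. Wavenumbers are stored in ascending
#' order internally; the conventional 4000 -> 450 cm^-1 display direction is a
#' presentation concern only. Input given in descending order is reversed
#' (pairs kept together).
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotonic, length >= 2.
#' @param ordinate Numeric vector of ordinate values, same length.
#' @param mode One of [ordinate_modes]. Percent modes must lie in (0, 100];
#'   absorbance and Kubelka-Munk values must be >= 0 is *not* required (noise
#'   and baseline correction may drive them negative), only finiteness is.
#' @param meta Optional named list of free-form metadata (resolution in cm^-1,
#'   scan count, sample id, mixture mass in mg, ...).
#'
#' @return An object of class `ir_spectrum`: a list with elements
#'   `wavenumbers`, `ordinate`, `mode`, `meta`.
#' @examples
#' s <- ir_spectrum(c(1726, 1730), c(44.8, 45.2), "percent_transmittance")
#' s
#' @export
ir_spectrum <- function(wavenumbers, ordinate, mode, meta = list()) {
  mode <- match.arg(mode, ordinate_modes)
  wavenumbers <- as.numeric(wavenumbers)
  ordinate <- as.numeric(ordinate)
  if (length(wavenumbers) != length(ordinate)) {
    stop("`wavenumbers` and `ordinate` must have the same length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (anyNA(wavenumbers) || anyNA(ordinate) ||
      any(!is.finite(wavenumbers)) || any(!is.finite(ordinate))) {
    stop("wavenumbers and ordinate values must be finite", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (all(d < 0)) { # descending input: flip to canonical ascending order
    wavenumbers <- rev(wavenumbers)
    ordinate <- rev(ordinate)
    d <- -rev(d)
  }
  if (any(d <= 0)) {
    if (anyDuplicated(wavenumbers)) {
      stop("duplicate wavenumbers in spectrum", call. = FALSE)
    }
    ord <- order(wavenumbers)
    wavenumbers <- wavenumbers[ord]
    ordinate <- ordinate[ord]
  }
  check_ordinate_range(ordinate, mode)
  structure(
    list(wavenumbers = wavenumbers, ordinate = ordinate,
         mode = mode, meta = meta),
    class = "ir_spectrum"
  )
}

check_ordinate_range <- function(ordinate, mode) {
  if (mode %in% c("percent_transmittance", "percent_reflectance")) {
    if (any(ordinate <= 0)) {
      stop(sprintf("%s values must be > 0 (log/Kubelka-Munk conversions are undefined at 0)",
                   mode), call. = FALSE)
    }
    if (any(ordinate > 100)) {
      stop(sprintf("%s values must be <= 100", mode), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.ir_spectrum <- function(x, ...) {
  wn <- x$wavenumbers
  cat(sprintf("<ir_spectrum> %d points, %.6g-%.6g cm-1, mode: %s\n",
              length(wn), min(wn), max(wn), x$mode))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.ir_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, ordinate = x$ordinate)
}

#' @export
length.ir_spectrum <- function(x) length(x$wavenumbers)

#' Construct an integration window
#'
#' An inclusive wavenumber interval, quoted high-to-low as spectroscopists
#' write them (e.g. the doxorubicin carbonyl window 1770-1680 cm^-1).
#'
#' @param high Upper wavenumber bound, cm^-1.
#' @param low Lower wavenumber bound, cm^-1. Must satisfy `high > low`.
#' @return An object of class `spectral_window` with fields `high`, `low`.
#' @examples
#' spectral_window(1770, 1680) # doxorubicin C=O analytical window
#' spectral_window(1690, 1630) # arterolane maleate amide C=O window
#' @export
spectral_window <- function(high, low) {
  high <- as.numeric(high); low <- as.numeric(low)
  stopifnot(length(high) == 1L, length(low) == 1L,
            is.finite(high), is.finite(low))
  if (high <= low) {
    stop("`high` must be strictly greater than `low`", call. = FALSE)
  }
  structure(list(high = high, low = low), class = "spectral_window")
}

#' @export
print.spectral_window <- function(x, ...) {
  cat(sprintf("<spectral_window> %.6g-%.6g cm-1\n", x$high, x$low))
  invisible(x)
}

#' Extract the grid points of a spectrum inside a window
#'
#' Returns the sub-spectrum of exactly the grid points with
#' `low <= wavenumber <= high` (endpoints inclusive where on-grid), keeping
#' mode and metadata. Never reorders or rescales ordinate values.
#'
#' @param s An [ir_spectrum].
#' @param w A [spectral_window].
#' @return An `ir_spectrum` restricted to the window.
#' @export
slice_window <- function(s, w) {
  stopifnot(inherits(s, "ir_spectrum"), inherits(w, "spectral_window"))
  keep <- s$wavenumbers >= w$low & s$wavenumbers <= w$high
  if (sum(keep) < 2L) {
    stop(sprintf("window too narrow for grid: %d point(s) in [%.6g, %.6g]",
                 sum(keep), w$low, w$high), call. = FALSE)
  }
  structure(
    list(wavenumbers = s$wavenumbers[keep], ordinate = s$ordinate[keep],
         mode = s$mode, meta = s$meta),
    class = "ir_spectrum"
  )
}
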