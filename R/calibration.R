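#' Fit a univariate least-squares calibration curve
#'
#' Ordinary least squares of band area on concentration, `area = S * conc + b`,
#' the standard-plot fit used for univariate IR quantification. The
#' coefficient of determination r^2 is reported; analytical tables often
#' label this quantity "correlation coefficient" but the values tabulated in
#' validation reports are r^2, and that is what is computed here.
#'
#' @param points A data frame (or tibble) with numeric columns
#'   `concentration` (%w/w, > 0) and `area` (band-area units). At least 3
#'   rows and 2 distinct concentrations are required.
#' @return An object of class `calibration_model`: list with `slope`,
#'   `intercept`, `r2`, `n_points`, `conc_range` (c(min, max) of the data),
#'   `sigma_intercept` (NA until set from replicate fits, see
#'   [replicate_intercept_sd()]), and the underlying `lm` fit.
#' @examples
#' pts <- tibble::tibble(
#'   concentration = c(0.6, 0.8, 1.0, 1.2, 1.4),
#'   area = c(2.131, 2.850, 3.521, 3.913, 4.601)
#' )
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("concentration", "area") %in% names(points))) {
    stop("`points` needs columns `concentration` and `area`", call. = FALSE)
  }
  conc <- as.numeric(points$concentration)
  area <- as.numeric(points$area)
  if (anyNA(conc) || anyNA(area)) stop("missing values in calibration points", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(conc) < 3L) stop("at least 3 calibration points required", call. = FALSE)
  if (length(unique(conc)) < 2L) {
    stop("singular design: all concentrations equal", call. = FALSE)
  }
  fit <- stats::lm(area ~ conc)
  # noiseless synthetic standards fit exactly; the perfect-fit warning from
  # summary.lm is expected there, not a defect
  smry <- suppressWarnings(summary(fit))
  structure(
    list(
      slope = unname(stats::coef(fit)[["conc"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r2 = smry$r.squared,
      n_points = length(conc),
      conc_range = range(conc),
      sigma_intercept = NA_real_,
      fit = fit
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> area = %.4g * conc + %.4g  (r2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n_points))
  cat(sprintf("  calibrated range: %.3g-%.3g %%w/w", x$conc_range[1], x$conc_range[2]))
  if (is.finite(x$sigma_intercept)) {
    cat(sprintf(";  sigma(intercept) = %.4g", x$sigma_intercept))
  }
  cat("\n")
  invisible(x)
}

#' Inverse prediction from a calibration curve
#'
#' Solves the fitted line for concentration, `c = (area - b) / S`.
#' Predictions outside the calibrated concentration range are flagged, not
#' rejected: beyond the verified Beer-Bouguer range the line is an
#' extrapolation, but routine assays may still use it deliberately.
#'
#' @param model A [fit_calibration()] model.
#' @param area Numeric vector of band areas.
#' @return A tibble with columns `area`, `concentration`, `out_of_range`.
#' @export
predict_concentration <- function(model, area) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope == 0) stop("calibration slope is zero", call. = FALSE)
  conc <- (as.numeric(area) - model$intercept) / model$slope
  tibble::tibble(
    area = as.numeric(area),
    concentration = conc,
    out_of_range = conc < model$conc_range[1] | conc > model$conc_range[2]
  )
}

#' Standard deviation of replicate calibration intercepts
#'
#' The sigma entering the detection/quantitation limits: the sample standard
#' deviation (n-1 denominator) of the y-intercepts of replicate calibration
#' fits, one fit per replicate set of standards.
#'
#' @param models A list of [fit_calibration()] models (>= 2).
#' @return Numeric sigma, in area units.
#' @export
replicate_intercept_sd <- function(models) {
  if (length(models) < 2L) {
    stop("at least 2 replicate calibration fits required", call. = FALSE)
  }
  if (!all(vapply(models, inherits, logical(1), "calibration_model"))) {
    stop("`models` must be a list of calibration_model objects", call. = FALSE)
  }
  stats::sd(vapply(models, `[[`, numeric(1), "intercept"))
}

#' Detection and quantitation limits from sigma and slope
#'
#' ICH Q2(R1) formulae based on the standard deviation of the response and
#' the calibration slope: `LOD = 3.3 * sigma / S`, `LOQ = 10 * sigma / S`,
#' so `LOQ = (10 / 3.3) * LOD` identically.
#'
#' @param sigma Standard deviation of the regression intercept, area units.
#' @param slope Calibration slope, area per %w/w; must be > 0.
#' @return Named list `lod`, `loq` in %w/w.
#' @examples
#' lod_loq(sigma = 0.1, slope = 3.0) # lod 0.11 %w/w
#' @export
lod_loq <- function(sigma, slope) {
  stopifnot(is.numeric(sigma), is.numeric(slope),
            length(sigma) == 1L, length(slope) == 1L)
  if (slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  list(lod = 3.3 * sigma / slope, loq = 10 * sigma / slope)
}

#' Residual standard error of the intercept of a single fit
#'
#' Alternative sigma for [lod_loq()] when replicate calibrations are not
#' available: the standard error of the intercept estimate from one fit.
#'
#' @param model A [fit_calibration()] model.
#' @return Numeric standard error, area units.
#' @export
intercept_se <- function(model) {
  stopifnot(inherits(model, "calibration_model"))
  unname(suppressWarnings(summary(model$fit))$coefficients["(Intercept)", "Std. Error"])
}
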