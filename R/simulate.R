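#' Define a synthetic absorption band
#'
#' Gaussian band used by the forward simulator: `strength` is the peak
#' height (ordinate units) contributed per 1 %w/w of analyte, `width` the
#' Gaussian standard deviation in cm^-1.
#'
#' @param center Band centre, cm^-1.
#' @param width Gaussian sd, cm^-1, > 0.
#' @param strength Peak height per %w/w, >= 0.
#' @return A `band_spec` object.
#' @export
band_spec <- function(center, width, strength) {
  stopifnot(is.numeric(center), is.numeric(width), is.numeric(strength),
            length(center) == 1L, length(width) == 1L, length(strength) == 1L)
  if (width <= 0) stop("band width must be > 0", call. = FALSE)
  if (strength < 0) stop("band strength must be >= 0", call. = FALSE)
  structure(list(center = center, width = width, strength = strength),
            class = "band_spec")
}

#' Assemble a drug spectral library
#'
#' A named set of synthetic bands with the analytical integration window and
#' the concentration range over which the linear (Beer-Lambert or
#' Kubelka-Munk) response holds. Exactly one band must fall inside the
#' analytical window: the analytical band.
#'
#' @param name Drug name.
#' @param bands List of [band_spec()] objects.
#' @param analytical_window A [spectral_window].
#' @param linear_range Numeric c(min, max) %w/w, min < max.
#' @param calibration_levels Standard concentrations, %w/w (default: five
#'   equally spaced levels across `linear_range`).
#' @return A `drug_library` object.
#' @export
drug_library <- function(name, bands, analytical_window, linear_range,
                         calibration_levels = seq(linear_range[1], linear_range[2],
                                                  length.out = 5)) {
  stopifnot(is.character(name), inherits(analytical_window, "spectral_window"),
            is.numeric(linear_range), length(linear_range) == 2L)
  if (!all(vapply(bands, inherits, logical(1), "band_spec"))) {
    stop("`bands` must be a list of band_spec objects", call. = FALSE)
  }
  if (linear_range[1] >= linear_range[2]) {
    stop("linear_range min must be < max", call. = FALSE)
  }
  centers <- vapply(bands, `[[`, numeric(1), "center")
  inside <- centers >= analytical_window$low & centers <= analytical_window$high
  if (sum(inside) != 1L) {
    stop(sprintf("exactly one band must lie inside the analytical window (found %d)",
                 sum(inside)), call. = FALSE)
  }
  structure(
    list(name = name, bands = bands, analytical_window = analytical_window,
         linear_range = linear_range, calibration_levels = calibration_levels,
         analytical_band = bands[[which(inside)]]),
    class = "drug_library"
  )
}

#' @export
print.drug_library <- function(x, ...) {
  cat(sprintf("<drug_library> %s: %d bands, analytical band %g cm-1, window %g-%g cm-1, linear %g-%g %%w/w\n",
              x$name, length(x$bands), x$analytical_band$center,
              x$analytical_window$high, x$analytical_window$low,
              x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Built-in doxorubicin hydrochloride library
#'
#' Band positions follow the drug's characteristic mid-IR assignments
#' (O-H/N-H/C-H stretches, the 1729 cm^-1 carbonyl stretch used for
#' quantification, aromatic C=C, C-O-C and ring bends). Relative strengths
#' and widths are simulator defaults: the analytical carbonyl band has unit
#' strength, the others 0.2-0.8.
#'
#' @return A [drug_library()] with analytical window 1770-1680 cm^-1 and
#'   linear range 0.6-1.4 %w/w.
#' @export
dox_library <- function() {
  b <- function(center, strength, width = 12) band_spec(center, width, strength)
  drug_library(
    name = "doxorubicin hydrochloride",
    bands = list(
      b(3525, 0.5, 30), b(3331, 0.6, 30),      # O-H / N-H stretch
      b(2935, 0.3), b(2897, 0.25),             # C-H stretch
      b(1729, 1.0),                            # C=O stretch (analytical)
      b(1617, 0.7), b(1582, 0.6), b(1414, 0.5),# C=C ring stretch
      b(1115, 0.45), b(1073, 0.4),             # C-O-C stretch
      b(805, 0.3), b(688, 0.2)                 # C=H / ring bend
    ),
    analytical_window = spectral_window(1770, 1680),
    linear_range = c(0.6, 1.4),
    calibration_levels = c(0.6, 0.8, 1.0, 1.2, 1.4)
  )
}

#' Built-in arterolane maleate library
#'
#' Band positions follow the drug's characteristic assignments (N-H and C-H
#' stretches, the 1650 cm^-1 amide carbonyl used for quantification, N-H
#' bends, C-H bend, C-N stretches); strengths and widths are simulator
#' defaults as in [dox_library()].
#'
#' @return A [drug_library()] with analytical window 1690-1630 cm^-1 and
#'   linear range 0.2-1.0 %w/w.
#' @export
alm_library <- function() {
  b <- function(center, strength, width = 12) band_spec(center, width, strength)
  drug_library(
    name = "arterolane maleate",
    bands = list(
      b(3278, 0.5, 30),                        # N-H stretch
      b(2930, 0.35), b(2858, 0.3),             # C-H stretch
      b(1650, 1.0),                            # amide C=O stretch (analytical)
      b(1571, 0.6), b(1500, 0.5),              # N-H bend
      b(1362, 0.4),                            # C-H bend
      b(1190, 0.35), b(1114, 0.3)              # C-N stretch
    ),
    analytical_window = spectral_window(1690, 1630),
    linear_range = c(0.2, 1.0),
    calibration_levels = c(0.2, 0.4, 0.6, 0.8, 1.0)
  )
}

#' A lactose-like excipient band set
#'
#' Synthetic excipient library for formulation simulations: broad hydroxyl
#' and C-H features plus fingerprint bands placed well away from both drugs'
#' analytical windows. Purely a simulator construct, not measured data.
#'
#' @return A list of [band_spec()] objects.
#' @export
lactose_like_excipients <- function() {
  list(
    band_spec(3400, 40, 0.30), # broad O-H envelope
    band_spec(2900, 20, 0.15),
    band_spec(1460, 15, 0.20),
    band_spec(1070, 18, 0.35),
    band_spec(920, 14, 0.10)
  )
}

#' Simulation configuration
#'
#' Conditions of a simulated measurement campaign. Defaults mirror the
#' acquisition the pipeline targets: 450-4000 cm^-1 grid at 4 cm^-1 point
#' spacing (half the 8 cm^-1 instrument resolution), 16-scan-level additive
#' noise of sd 0.001 in the linear ordinate, a small sloped background, and
#' a sample-mass response sensitivity that is stronger for pressed pellets
#' (transmittance, 65 mg nominal) than for the DRIFTS cup (reflectance,
#' 70 mg nominal).
#'
#' @param grid_from,grid_to,grid_step Wavenumber grid, cm^-1.
#' @param noise_sd Additive Gaussian noise sd applied in the linear signal
#'   domain (absorbance / Kubelka-Munk), not in %T/%R.
#' @param baseline_offset,baseline_slope Background `offset + slope * nu`
#'   added to the linear signal (removed exactly by the chord baseline).
#' @param matrix_bands Optional list of [band_spec()] for a constant matrix
#'   contribution.
#' @param mass_sensitivity Named numeric: fractional response change per mg
#'   deviation from the nominal sample mass, per mode.
#' @param nominal_mass Named numeric: nominal sample mass, mg, per mode.
#' @param mixture_mass Actual sample mass, mg, or `NULL` for nominal.
#' @param seed Integer seed pinning all noise draws; `NULL` uses the ambient
#'   RNG state (for callers that manage their own stream).
#' @return A `sim_config` object.
#' @export
sim_config <- function(grid_from = 450, grid_to = 4000, grid_step = 4,
                       noise_sd = 0.001,
                       baseline_offset = 0.05, baseline_slope = 1e-5,
                       matrix_bands = list(),
                       mass_sensitivity = c(transmittance = 0.02,
                                            reflectance = 0.005),
                       nominal_mass = c(transmittance = 65, reflectance = 70),
                       mixture_mass = NULL,
                       seed = 1L) {
  stopifnot(grid_step > 0, grid_to > grid_from, noise_sd >= 0)
  structure(
    list(grid_from = grid_from, grid_to = grid_to, grid_step = grid_step,
         noise_sd = noise_sd, baseline_offset = baseline_offset,
         baseline_slope = baseline_slope, matrix_bands = matrix_bands,
         mass_sensitivity = mass_sensitivity, nominal_mass = nominal_mass,
         mixture_mass = mixture_mass, seed = seed),
    class = "sim_config"
  )
}

sim_grid <- function(cfg) seq(cfg$grid_from, cfg$grid_to, by = cfg$grid_step)

mass_factor <- function(cfg, channel) {
  nominal <- cfg$nominal_mass[[channel]]
  actual <- if (is.null(cfg$mixture_mass)) nominal else cfg$mixture_mass
  1 + cfg$mass_sensitivity[[channel]] * (actual - nominal)
}

bands_profile <- function(wn, bands) {
  if (!length(bands)) return(numeric(length(wn)))
  Reduce(`+`, lapply(bands, function(b) {
    b$strength * exp(-(wn - b$center)^2 / (2 * b$width^2))
  }))
}

# Run expr with a pinned RNG state, restoring the caller's stream afterwards;
# seed = NULL leaves the ambient stream in use (and advanced).
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Linear-domain forward model shared by both instrument modes. The clamp at
# zero keeps %T/%R physical; with the default background offset it is never
# active (the offset sits 10 noise sd above zero).
linear_profile <- function(lib, conc, cfg, channel,
                           extra_bands = list()) {
  if (conc < 0) stop("concentration must be >= 0", call. = FALSE)
  wn <- sim_grid(cfg)
  signal <- mass_factor(cfg, channel) * conc *
    bands_profile(wn, lib$bands)
  drift <- cfg$baseline_offset + cfg$baseline_slope * wn
  matrix_part <- bands_profile(wn, cfg$matrix_bands) +
    bands_profile(wn, extra_bands)
  noise <- if (cfg$noise_sd > 0) stats::rnorm(length(wn), 0, cfg$noise_sd) else 0
  pmax(signal + drift + matrix_part + noise, 0)
}

#' Noiseless-free forward model in absorbance units
#'
#' Builds the Beer-Lambert-linear absorbance spectrum
#' `A(nu) = mass_factor * conc * sum_i strength_i * exp(-(nu - center_i)^2 /
#' (2 width_i^2)) + drift(nu) + matrix(nu) + noise(nu)` with i.i.d. Gaussian
#' noise pinned to the configuration seed.
#'
#' @param lib A [drug_library()].
#' @param conc Concentration, %w/w, >= 0.
#' @param cfg A [sim_config()].
#' @return An [ir_spectrum] in `absorbance` mode.
#' @export
absorbance_profile <- function(lib, conc, cfg = sim_config()) {
  a <- with_sim_seed(cfg$seed, linear_profile(lib, conc, cfg, "transmittance"))
  ir_spectrum(sim_grid(cfg), a, "absorbance",
              meta = list(drug = lib$name, conc_pct_ww = conc,
                          resolution_cm1 = 8, scans = 16))
}

#' Simulate a KBr-pellet transmittance spectrum
#'
#' `%T = 100 * 10^(-A)` from the absorbance forward model; values lie in
#' (0, 100].
#'
#' @inheritParams absorbance_profile
#' @return An [ir_spectrum] in `percent_transmittance` mode.
#' @export
generate_transmittance_spectrum <- function(lib, conc, cfg = sim_config()) {
  absorbance_to_transmittance(absorbance_profile(lib, conc, cfg))
}

#' Simulate a DRIFTS reflectance spectrum
#'
#' The forward model is built in Kubelka-Munk units (noise applied there,
#' where the calibration is linear) and inverted to `%R` via
#' [km_to_reflectance()]; values lie in (0, 100].
#'
#' @inheritParams absorbance_profile
#' @return An [ir_spectrum] in `percent_reflectance` mode.
#' @export
generate_reflectance_spectrum <- function(lib, conc, cfg = sim_config()) {
  f <- with_sim_seed(cfg$seed, linear_profile(lib, conc, cfg, "reflectance"))
  km <- ir_spectrum(sim_grid(cfg), f, "kubelka_munk",
                    meta = list(drug = lib$name, conc_pct_ww = conc,
                                resolution_cm1 = 8, scans = 16))
  km_to_reflectance(km)
}

#' Simulate a replicated calibration set with known truth
#'
#' Generates `replicates` spectra at each standard concentration with fresh
#' noise draws from a single seed-pinned stream, so an identical
#' configuration reproduces the set exactly. The truth record carries two
#' slopes: `slope_analytic`, the closed-form Gaussian area of the analytical
#' band per unit concentration (`strength * width * sqrt(2*pi)`), and
#' `slope_protocol`, the area per unit concentration actually delivered by
#' the quantification protocol (noiseless simulated spectrum, chord baseline
#' and trapezoid over the analytical window). The two differ by the window
#' truncation and the chord's clipping of the band tails (about half a
#' percent at the default band width); estimator-recovery checks compare
#' against `slope_protocol`, the slope of the measurement process itself.
#'
#' @param lib A [drug_library()].
#' @param concentrations Standard levels, %w/w (default the library's).
#' @param replicates Spectra per level (default 3).
#' @param mode `"transmittance"` or `"reflectance"`.
#' @param cfg A [sim_config()].
#' @return List with `spectra` (list of [ir_spectrum]), `design` (tibble:
#'   `level`, `replicate`), and `truth` (list: `slope_analytic`,
#'   `slope_protocol`, `intercept_protocol`, `mode`, `window`).
#' @export
generate_calibration_set <- function(lib,
                                     concentrations = lib$calibration_levels,
                                     replicates = 3L,
                                     mode = c("transmittance", "reflectance"),
                                     cfg = sim_config()) {
  mode <- match.arg(mode)
  if (!length(concentrations)) stop("no concentration levels given", call. = FALSE)
  gen <- switch(mode,
                transmittance = generate_transmittance_spectrum,
                reflectance = generate_reflectance_spectrum)
  design <- expand.grid(replicate = seq_len(replicates),
                        level = concentrations)[, c("level", "replicate")]
  cfg_free <- cfg; cfg_free$seed <- NULL
  spectra <- with_sim_seed(cfg$seed, {
    lapply(seq_len(nrow(design)), function(i) {
      s <- gen(lib, design$level[[i]], cfg_free)
      s$meta$replicate <- design$replicate[[i]]
      s
    })
  })
  cfg_clean <- cfg; cfg_clean$noise_sd <- 0; cfg_clean$seed <- NULL
  w <- lib$analytical_window
  a1 <- quantify(gen(lib, 1, cfg_clean), w)$value
  a0 <- quantify(gen(lib, 0, cfg_clean), w)$value
  ab <- lib$analytical_band
  list(
    spectra = spectra,
    design = tibble::as_tibble(design),
    truth = list(
      slope_analytic = ab$strength * ab$width * sqrt(2 * pi),
      slope_protocol = a1 - a0,
      intercept_protocol = a0,
      mode = mode,
      window = w
    )
  )
}

#' Simulate a formulation spectrum with excipient bands
#'
#' Adds excipient bands to the drug forward model in the chosen instrument
#' mode. By default each excipient centre must sit at least three of its own
#' widths outside the drug's analytical window, the condition under which
#' the assay is interference-free. Violations raise a warning and flag the
#' returned spectrum (`meta$overlap_flag`); `allow_overlap = TRUE` suppresses
#' the warning but the flag is still set.
#'
#' @inheritParams generate_calibration_set
#' @param conc Drug concentration, %w/w.
#' @param excipient_bands List of [band_spec()] (default
#'   [lactose_like_excipients()]).
#' @param allow_overlap If `TRUE`, overlapping excipients are permitted
#'   without a warning (the flag is still set).
#' @return An [ir_spectrum] in the raw ordinate of the chosen mode.
#' @export
generate_formulation_spectrum <- function(lib, conc,
                                          excipient_bands = lactose_like_excipients(),
                                          mode = c("transmittance", "reflectance"),
                                          cfg = sim_config(),
                                          allow_overlap = FALSE) {
  mode <- match.arg(mode)
  w <- lib$analytical_window
  overlap <- vapply(excipient_bands, function(b) {
    b$center > w$low - 3 * b$width && b$center < w$high + 3 * b$width
  }, logical(1))
  if (any(overlap) && !allow_overlap) {
    warning(sprintf("excipient band(s) at %s cm-1 overlap the analytical window",
                    paste(vapply(excipient_bands[overlap], `[[`, numeric(1), "center"),
                          collapse = ", ")), call. = FALSE)
  }
  channel <- mode
  s <- with_sim_seed(cfg$seed, {
    y <- linear_profile(lib, conc, cfg, channel, extra_bands = excipient_bands)
    if (mode == "transmittance") {
      ir_spectrum(sim_grid(cfg), 100 * 10^(-y), "percent_transmittance")
    } else {
      km_to_reflectance(ir_spectrum(sim_grid(cfg), y, "kubelka_munk"))
    }
  })
  s$meta <- list(drug = lib$name, conc_pct_ww = conc,
                 resolution_cm1 = 8, scans = 16,
                 overlap_flag = any(overlap))
  s
}
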