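test_that("built-in libraries have one analytical band inside their window", {
  for (lib in list(dox_library(), alm_library())) {
    centers <- vapply(lib$bands, `[[`, numeric(1), "center")
    inside <- centers >= lib$analytical_window$low &
      centers <= lib$analytical_window$high
    expect_equal(sum(inside), 1L)
    expect_equal(lib$analytical_band$center, centers[inside])
  }
  expect_equal(dox_library()$analytical_band$center, 1729)
  expect_equal(alm_library()$analytical_band$center, 1650)
  expect_error(drug_library("bad", list(band_spec(1000, 10, 1)),
                            spectral_window(1770, 1680), c(0.5, 1.5)),
               "exactly one band")
})

test_that("the clean forward model is zero at zero concentration", {
  lib <- dox_library()
  a <- absorbance_profile(lib, 0, clean_cfg())
  expect_true(all(a$ordinate == 0))
  expect_true(all(generate_transmittance_spectrum(lib, 0, clean_cfg())$ordinate == 100))
  expect_true(all(generate_reflectance_spectrum(lib, 0, clean_cfg())$ordinate == 100))
  expect_error(absorbance_profile(lib, -1, clean_cfg()), ">= 0")
})

test_that("band centre amplitudes equal concentration times strength", {
  lib <- dox_library()
  # put the 1729 cm-1 centre exactly on the grid (449 + 4k passes through it)
  cfg <- clean_cfg(grid_from = 449)
  a <- absorbance_profile(lib, 0.8, cfg)
  i <- which(a$wavenumbers == 1729)
  expect_length(i, 1L)
  # the 1729 band is isolated: neighbours are > 9 widths away
  expect_equal(a$ordinate[i], 0.8 * 1.0, tolerance = 1e-6)
})

test_that("the profile's analytical-window integral matches the Gaussian area", {
  # isolated analytical band on a fine grid: plain trapezoid, no chord
  lib <- dox_library()
  cfg <- clean_cfg(grid_step = 2)
  a <- absorbance_profile(lib, 1.0, cfg)
  sub <- slice_window(a, lib$analytical_window)
  x <- sub$wavenumbers; y <- sub$ordinate
  plain <- sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  ab <- lib$analytical_band
  expect_equal(plain, ab$strength * ab$width * sqrt(2 * pi), tolerance = 5e-3)
})

test_that("transmittance decreases monotonically with concentration at the band", {
  lib <- dox_library()
  cfg <- clean_cfg()
  t_at_band <- vapply(c(0.6, 0.8, 1.0, 1.2, 1.4), function(conc) {
    s <- generate_transmittance_spectrum(lib, conc, cfg)
    s$ordinate[which.min(abs(s$wavenumbers - 1729))]
  }, numeric(1))
  expect_true(all(diff(t_at_band) < 0))
})

test_that("reflectance spectra are exact KM inverses even with noise", {
  lib <- alm_library()
  cfg <- sim_config(noise_sd = 0.001, seed = 31)
  r <- generate_reflectance_spectrum(lib, 0.6, cfg)
  expect_identical(r$mode, "percent_reflectance")
  expect_true(all(r$ordinate > 0 & r$ordinate <= 100))
  back <- km_to_reflectance(reflectance_to_km(r))
  expect_equal(back$ordinate, r$ordinate, tolerance = 1e-10)
  # noiseless KM ordinate equals the absorbance forward model at nominal mass
  km <- reflectance_to_km(generate_reflectance_spectrum(lib, 0.6, clean_cfg()))
  expect_equal(km$ordinate, absorbance_profile(lib, 0.6, clean_cfg())$ordinate,
               tolerance = 1e-10)
})

test_that("identical configuration reproduces identical spectra", {
  lib <- dox_library()
  cfg <- sim_config(seed = 99)
  s1 <- generate_transmittance_spectrum(lib, 1.0, cfg)
  s2 <- generate_transmittance_spectrum(lib, 1.0, cfg)
  expect_identical(s1, s2)
  set1 <- generate_calibration_set(lib, cfg = cfg)
  set2 <- generate_calibration_set(lib, cfg = cfg)
  expect_identical(set1, set2)
  # replicates within a set carry fresh noise
  expect_false(identical(set1$spectra[[1]]$ordinate, set1$spectra[[2]]$ordinate))
})

test_that("noiseless calibration sets are exactly linear with the protocol slope", {
  for (lib in list(dox_library(), alm_library())) {
    for (mode in c("transmittance", "reflectance")) {
      set <- generate_calibration_set(lib, replicates = 1, mode = mode,
                                      cfg = clean_cfg())
      w <- lib$analytical_window
      areas <- vapply(set$spectra, function(s) quantify(s, w)$value, numeric(1))
      m <- fit_calibration(tibble::tibble(concentration = set$design$level,
                                          area = areas))
      expect_equal(m$r2, 1, tolerance = 1e-9)
      expect_equal(m$slope, set$truth$slope_protocol, tolerance = 1e-6)
      # protocol slope matches the continuous chord-protocol closed form
      # evaluated at the realised on-grid window edges
      grid <- seq(450, 4000, by = 4)
      inside <- grid[grid >= w$low & grid <= w$high]
      ab <- lib$analytical_band
      expect_equal(set$truth$slope_protocol,
                   chord_protocol_area(ab$center, ab$width, ab$strength,
                                       min(inside), max(inside)),
                   tolerance = 5e-3)
    }
  }
  # for the doxorubicin window the chord clips under 1% of the Gaussian area
  set <- generate_calibration_set(dox_library(), replicates = 1, cfg = clean_cfg())
  expect_equal(set$truth$slope_protocol, set$truth$slope_analytic,
               tolerance = 1e-2)
})

test_that("spectrum-level noise leaves the calibration slope unbiased", {
  lib <- dox_library()
  w <- lib$analytical_window
  slopes <- vapply(1:60, function(k) {
    set <- generate_calibration_set(lib, replicates = 1,
                                    cfg = sim_config(seed = 1000 + k))
    areas <- vapply(set$spectra, function(s) quantify(s, w)$value, numeric(1))
    fit_calibration(tibble::tibble(concentration = set$design$level,
                                   area = areas))$slope
  }, numeric(1))
  truth <- generate_calibration_set(lib, replicates = 1,
                                    cfg = clean_cfg())$truth$slope_protocol
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - truth), 3 * se_mean)
})

test_that("formulation spectra are interference-free for excluded excipients", {
  lib <- dox_library()
  w <- lib$analytical_window
  cfg <- clean_cfg()
  # excipient-only mix: the analytical window carries essentially no area
  s0 <- generate_formulation_spectrum(lib, 0, mode = "transmittance", cfg = cfg)
  a0 <- quantify(s0, w)$value
  unit <- quantify(generate_transmittance_spectrum(lib, 1, cfg), w)$value
  expect_lt(abs(a0), 1e-3 * unit)
  # adding excipients does not move the drug's quantified area
  s1 <- generate_formulation_spectrum(lib, 1.0, mode = "transmittance", cfg = cfg)
  expect_equal(quantify(s1, w)$value, unit, tolerance = 5e-3)
  expect_false(s1$meta$overlap_flag)
  # an overlapping excipient is flagged and warned about
  expect_warning(
    sflag <- generate_formulation_spectrum(
      lib, 1.0, excipient_bands = list(band_spec(1700, 12, 0.2)),
      mode = "transmittance", cfg = cfg),
    "overlap")
  expect_true(sflag$meta$overlap_flag)
})

test_that("a noiseless synthetic assay recovers 100% purity", {
  lib <- alm_library()
  w <- lib$analytical_window
  cfg <- clean_cfg()
  set <- generate_calibration_set(lib, replicates = 1, mode = "reflectance",
                                  cfg = cfg)
  areas <- vapply(set$spectra, function(s) quantify(s, w)$value, numeric(1))
  m <- fit_calibration(tibble::tibble(concentration = set$design$level,
                                      area = areas))
  s <- generate_formulation_spectrum(lib, 0.6, mode = "reflectance", cfg = cfg)
  conc <- predict_concentration(m, quantify(s, w)$value)$concentration
  purity <- assay_formulation(conc, 0.6, 150)$purity_pct
  expect_equal(purity, 100, tolerance = 0.5)
})
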