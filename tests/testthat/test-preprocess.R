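make_spec <- function(y, mode = "absorbance", x = seq_along(y) - 1) {
  ir_spectrum(x, y, mode)
}

test_that("transmittance/absorbance conversion follows the log law and inverts", {
  s <- make_spec(c(100, 10, 1), "percent_transmittance")
  a <- transmittance_to_absorbance(s)
  expect_identical(a$mode, "absorbance")
  expect_equal(a$ordinate, c(0, 1, 2))
  expect_equal(a$wavenumbers, s$wavenumbers)

  set.seed(11)
  t0 <- runif(50, 0.5, 100)
  rt <- absorbance_to_transmittance(transmittance_to_absorbance(
    make_spec(t0, "percent_transmittance")))
  expect_equal(rt$ordinate, t0, tolerance = 1e-12)

  expect_error(transmittance_to_absorbance(make_spec(c(1, 2), "absorbance")),
               "not in percent_transmittance")
})

test_that("Kubelka-Munk transform matches the remission function and inverts", {
  s <- make_spec(c(100, 50, 10), "percent_reflectance")
  f <- reflectance_to_km(s)
  expect_identical(f$mode, "kubelka_munk")
  expect_equal(f$ordinate, c(0, 0.25, 4.05))

  for (fv in c(0.01, 1, 10)) {
    km <- make_spec(c(fv, fv), "kubelka_munk")
    expect_equal(reflectance_to_km(km_to_reflectance(km))$ordinate,
                 c(fv, fv), tolerance = 1e-10)
  }
  expect_equal(km_to_reflectance(make_spec(c(0, 0.25), "kubelka_munk"))$ordinate,
               c(100, 50))

  expect_error(km_to_reflectance(make_spec(c(-0.1, 1), "kubelka_munk")), ">= 0")
})

test_that("KM round trip and monotonicity hold over random reflectances", {
  set.seed(42)
  for (i in 1:20) {
    r <- sort(runif(30, 0.001, 1)) * 100
    s <- make_spec(r, "percent_reflectance")
    back <- km_to_reflectance(reflectance_to_km(s))
    expect_equal(back$ordinate, r, tolerance = 1e-10)
    # f(R) strictly decreasing in R
    f <- reflectance_to_km(s)$ordinate
    expect_true(all(diff(f) < 0))
  }
})

test_that("chord baseline zeroes constants, ramps, and leaves centred peaks", {
  w <- spectral_window(4, 0)
  expect_equal(chord_baseline(make_spec(rep(3, 5)), w)$ordinate, rep(0, 5))
  expect_equal(chord_baseline(make_spec(2 + 0.5 * (0:4)), w)$ordinate, rep(0, 5))
  expect_equal(chord_baseline(make_spec(c(0, 0, 2, 0, 0)), w)$ordinate,
               c(0, 0, 2, 0, 0))
  expect_error(chord_baseline(make_spec(c(1, 100), "percent_transmittance"), w),
               "absorbance or kubelka_munk")
})

test_that("band_area integrates by trapezoid after the chord", {
  w <- spectral_window(4, 0)
  expect_equal(band_area(make_spec(rep(1, 5)), w)$value, 0)
  tri <- band_area(make_spec(c(0, 0, 2, 0, 0)), w)
  expect_equal(tri$value, 2.0) # hand trapezoid: 0 + 1 + 1 + 0
  expect_identical(tri$mode_used, "absorbance")
})

test_that("band_area reproduces the Gaussian closed form on a fine grid", {
  a <- 1.7; wd <- 10
  x <- seq(-6 * wd, 6 * wd, by = wd / 4)
  s <- ir_spectrum(x, a * exp(-x^2 / (2 * wd^2)), "absorbance")
  got <- band_area(s, spectral_window(6 * wd, -6 * wd))$value
  expect_equal(got, a * wd * sqrt(2 * pi), tolerance = 1e-3)
})

test_that("band_area is invariant to affine baselines", {
  set.seed(3)
  x <- seq(1600, 1800, by = 4)
  base <- exp(-(x - 1700)^2 / (2 * 15^2))
  w <- spectral_window(1780, 1620)
  a0 <- band_area(ir_spectrum(x, base, "absorbance"), w)$value
  for (i in 1:10) {
    off <- runif(1, -5, 5); slp <- runif(1, -0.01, 0.01)
    a1 <- band_area(ir_spectrum(x, base + off + slp * x, "absorbance"), w)$value
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("quantify runs the full chain in both instrument modes", {
  x <- seq(1600, 1800, by = 4)
  w <- spectral_window(1780, 1620)
  flat <- ir_spectrum(x, rep(100, length(x)), "percent_transmittance")
  expect_equal(quantify(flat, w)$value, 0)

  # homogeneity: doubling concentration doubles the area (noiseless model)
  lib <- dox_library()
  wdx <- lib$analytical_window
  cfg <- clean_cfg()
  for (mode in c("transmittance", "reflectance")) {
    gen <- if (mode == "transmittance") generate_transmittance_spectrum
           else generate_reflectance_spectrum
    a1 <- quantify(gen(lib, 0.7, cfg), wdx)$value
    a2 <- quantify(gen(lib, 1.4, cfg), wdx)$value
    expect_equal(a2 / a1, 2, tolerance = 1e-6)
  }
})

test_that("quantify on a synthetic standard matches the closed-form protocol oracle", {
  lib <- dox_library()
  s <- generate_transmittance_spectrum(lib, 1.0, clean_cfg())
  got <- quantify(s, lib$analytical_window)$value
  ab <- lib$analytical_band
  # window edges as realised on the 450 + 4k grid
  grid <- seq(450, 4000, by = 4)
  inside <- grid[grid >= 1680 & grid <= 1770]
  oracle <- chord_protocol_area(ab$center, ab$width, ab$strength,
                                min(inside), max(inside))
  expect_equal(got, oracle, tolerance = 5e-4)
  # the plain Gaussian area differs only by window truncation + chord clipping
  expect_equal(got, ab$strength * ab$width * sqrt(2 * pi), tolerance = 1e-2)
})
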