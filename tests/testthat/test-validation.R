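test_that("percent RSD matches hand computation and is scale-invariant", {
  expect_equal(percent_rsd(c(5, 5, 5)), 0)
  expect_equal(percent_rsd(c(1, 2, 3)), 50) # mean 2, sample sd 1
  set.seed(8)
  v <- runif(6, 1, 10)
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(percent_rsd(k * v), percent_rsd(v), tolerance = 1e-12)
  }
  expect_error(percent_rsd(5), "2 values")
  expect_error(percent_rsd(c(-1, 1)), "mean is zero")
})

test_that("the two recovery formulas reproduce the worked records", {
  # bundled arterolane transmittance records: totals over nominal
  r <- reference_recovery("ALM", "transmittance")
  expect_equal(recovery_overall(r$cu, r$ca, r$cv),
               c(93.0, 91.66667, 92.1), tolerance = 1e-5)
  # the spike-only formula tells a different story on the same first record
  expect_equal(recovery_standard_addition(r$cu[1], r$ca[1], r$cv[1]), 72.0)

  expect_equal(recovery_overall(0.5, 0.5, 1.0), 100)
  expect_equal(recovery_standard_addition(0.5, 0.5, 1.0), 100)
  expect_equal(recovery_standard_addition(0.3, 0.2, 0.3), 0) # cv == cu
  expect_error(recovery_standard_addition(0.1, 0, 0.2), "> 0")
  expect_error(recovery_overall(0, 0, 0), "> 0")
})

test_that("the recovery formulas coincide exactly when cv = cu + ca", {
  set.seed(5)
  for (i in 1:10) {
    cu <- runif(1, 0, 1); ca <- runif(1, 0.05, 1)
    expect_equal(recovery_overall(cu, ca, cu + ca), 100, tolerance = 1e-12)
    expect_equal(recovery_standard_addition(cu, ca, cu + ca), 100,
                 tolerance = 1e-12)
    # and diverge otherwise (unless cu = 0)
    cv <- 0.9 * (cu + ca)
    expect_false(isTRUE(all.equal(recovery_overall(cu, ca, cv),
                                  recovery_standard_addition(cu, ca, cv))))
  }
})

test_that("stock-aliquot bookkeeping gives the expected drug masses", {
  expect_equal(mix_mass_to_concentration(3.0, 0.05)$drug_mg, 0.15)
  expect_equal(mix_mass_to_concentration(3.0, 0.05)$conc_pct_ww, 0.15)
  expect_equal(mix_mass_to_concentration(5.0, 0.10)$drug_mg, 0.5)
  expect_equal(mix_mass_to_concentration(10, 0.5)$drug_mg, 5.0)
  # multiple aliquots add their contributions
  expect_equal(mix_mass_to_concentration(c(5, 1), 0.10)$drug_mg, 0.6)
  expect_error(mix_mass_to_concentration(120, 0.1), "exceed")
  expect_error(mix_mass_to_concentration(5, 1.2), "fraction")
})

test_that("precision summary separates intra- and inter-day dispersion", {
  grid <- expand.grid(level = c(0.6, 1.0), day = 1:2, replicate = 1:3)
  grid$value <- 7
  p <- precision_summary(grid)
  expect_equal(p$per_level$intra_day_rsd, c(0, 0))
  expect_equal(p$per_level$inter_day_rsd, c(0, 0))

  g2 <- data.frame(level = 1, day = rep(1:2, each = 2),
                   replicate = c(1, 2, 1, 2), value = c(1, 1, 3, 3))
  p2 <- precision_summary(g2)
  expect_equal(p2$per_day$rsd, c(0, 0))
  expect_equal(p2$per_level$inter_day_rsd, 100 * sd(c(1, 1, 3, 3)) / 2,
               tolerance = 1e-6) # 57.735
  expect_error(precision_summary(data.frame(level = 1, day = 1,
                                            replicate = 1:3, value = 1:3)),
               "fewer than 2 days")
})

test_that("duplicating a day leaves inter-day dispersion at the intra-day value", {
  # with sample (n-1) SDs, duplicating a day of n replicates rescales the
  # pooled SD by sqrt(2(n-1)/(2n-1)); the day-to-day component is exactly zero
  set.seed(21)
  v <- rnorm(3, 10, 0.1)
  g <- data.frame(level = 1, day = rep(1:2, each = 3), replicate = rep(1:3, 2),
                  value = rep(v, 2))
  p <- precision_summary(g)
  expect_equal(p$per_day$rsd, rep(p$per_level$intra_day_rsd, 2))
  n <- 3
  expect_equal(p$per_level$inter_day_rsd,
               p$per_level$intra_day_rsd * sqrt(2 * (n - 1) / (2 * n - 1)),
               tolerance = 1e-9)
})

test_that("robustness summary is the RSD across mass variants", {
  r <- data.frame(level = rep(1, 3), mix_mass_mg = c(63, 65, 67),
                  value = c(10, 10, 10))
  expect_equal(robustness_summary(r)$rsd, 0)
  r$value <- c(10.0, 10.1, 9.9)
  expect_equal(robustness_summary(r)$rsd, 1.0) # mean 10, sd 0.1
  r2 <- data.frame(level = 1, mix_mass_mg = 65, value = 10)
  expect_error(robustness_summary(r2), "fewer than 2 mass")
})

test_that("assay purity follows measured over nominal and ignores mass units", {
  a <- assay_formulation(1.0, 1.0, 150)
  expect_equal(a$purity_pct, 100)
  expect_equal(a$amount_found, 150)

  expect_equal(assay_formulation(0.96073333, 1, 150)$amount_found, 144.11,
               tolerance = 1e-4)
  # purity is dimensionless: label claim in mg or g gives the same %
  p_mg <- assay_formulation(0.93, 1.0, 10)$purity_pct
  p_g <- assay_formulation(0.93, 1.0, 0.010)$purity_pct
  expect_equal(p_mg, p_g)
  expect_error(assay_formulation(1, 0, 10), "> 0")
})
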