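Package: mirquant
Title: Quantitative Mid-Infrared Spectroscopy with ICH Q2(R1) Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Univariate quantification of solid drug preparations from
    mid-infrared spectra recorded in transmittance (KBr pellet) or diffuse
    reflectance (DRIFTS) mode. Converts raw ordinates to absorbance or the
    Kubelka-Munk function, applies a two-point chord baseline, integrates
    band areas over an analytical window, fits least-squares calibration
    curves, and computes the ICH Q2(R1) validation statistics: linearity,
    accuracy (two recovery formulas), repeatability and intermediate
    precision as percent relative standard deviation, detection and
    quantitation limits (3.3*sigma/S and 10*sigma/S), robustness to sample
    mass perturbation, and formulation assay. A forward simulator of
    powder-mixture spectra with Gaussian bands, Beer-Lambert or
    Kubelka-Munk linear response, baseline drift, mass sensitivity and
    seeded noise makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
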