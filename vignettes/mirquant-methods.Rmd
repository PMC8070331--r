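---
title: "Quantitative mid-IR assay methodology in mirquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative mid-IR assay methodology in mirquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirquant)
```

## The measurement model

`mirquant` implements univariate quantification of a solid analyte dispersed
in a non-absorbing matrix (KBr), measured in the mid-IR in one of two
instrument modes.

**Transmittance (KBr pellet).** The Beer–Lambert law states that absorbance,
$A(\nu) = 2 - \log_{10}\%T(\nu)$, is proportional to analyte concentration
at fixed path length. The assumptions are the usual ones: homogeneous
dispersion, constant pellet mass (path length), no detector saturation, and
an analyte band resolvable from the matrix. The method is empirical — the
calibration absorbs any proportionality constants — but linearity in
concentration is only expected in the absorbance ordinate, which is why
band areas are integrated there rather than in raw %T (a `area_ordinate =
"raw"` switch in `quantify()` preserves the alternative for comparison with
vendor software).

**Diffuse reflectance (DRIFTS).** For an optically thick powder bed the
Kubelka–Munk remission function
$f(R) = (1-R)^2 / 2R$, $R = \%R/100$,
is approximately proportional to the ratio of absorption to scattering
coefficients, hence to concentration when the scattering of the bed is
dominated by the constant matrix. The inverse,
$R = 1 + f - \sqrt{f^2 + 2f}$, is used by the simulator and is exact on
$f \ge 0$. KM linearity degrades with particle-size, packing and humidity
effects; none of these are modelled (see Limitations).

**Band area.** Both chains then share one quantification step: slice the
analytical window, subtract the two-point chord through the window-endpoint
ordinates, and integrate the residual by the trapezoidal rule. The chord
removes any affine (offset + slope) background exactly; that invariance is
property-tested. Areas are carried in ordinate·cm⁻¹; instrument software
displays the same quantity in arbitrary units (mm² on screen), and every
downstream statistic — r², recovery, %RSD, LOD, purity — is invariant to
that fixed scale factor, which is also property-tested.

**Calibration and validation.** The standard plot is ordinary least squares
of area on concentration; r² is reported (validation tables sometimes label
this "correlation coefficient", but the tabulated values are coefficients
of determination). Validation statistics follow ICH Q2(R1): recovery,
precision as %RSD with the sample (n−1) standard deviation throughout,
LOD = 3.3σ/S and LOQ = 10σ/S, robustness, and assay against label claim.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| grid spacing | 4 | cm⁻¹ | half the 8 cm⁻¹ instrument resolution; spacing is not dictated by resolution, so it is configurable |
| analytical windows | 1770–1680 (DOX), 1690–1630 (ALM) | cm⁻¹ | the carbonyl-band integration windows of the two built-in methods; endpoints inclusive |
| chord endpoint width `m` | 1 | points | plain two-point chord; larger `m` averages noise at the anchors |
| band width | 12 (30 for X–H stretches) | cm⁻¹ (Gaussian sd) | typical condensed-phase mid-IR bandwidths; only band *positions* are measured quantities, widths and relative strengths are simulator conventions |
| `noise_sd` | 0.001 | absorbance / KM units | chosen so the induced band-area %RSD (≈0.3–0.6%) falls in the 0.2–1.3% range that replicate measurements of this kind show at 16 scans and 8 cm⁻¹; note the chord makes the two window endpoints enter the area with weights ≈ −W/2, so area noise is dominated by them |
| baseline | 0.05 + 1e-5·ν | linear ordinate | instruments never sit at exactly zero ordinate; the offset also keeps the physical clamp at zero inactive (it sits many noise sd above zero), so the noise model stays exactly additive |
| mass sensitivity | 0.02 (pellet), 0.005 (cup) | fraction per mg | echoes the observed behaviour that transmittance responds at the few-%-per-mg level to pellet-mass changes while the DRIFTS cup is much less sensitive; with ±2 mg perturbations these defaults yield robustness %RSD ≈ 4% vs ≈ 1%, the reported ordering |
| `day_effect_sd` | 0.003 | fraction | a small multiplicative between-day response factor so intermediate precision exceeds repeatability on average while both remain < 2% RSD; no between-day variance component is measured anywhere, so this is a simulator convention |
| σ for LOD/LOQ | replicate-intercept SD | area | each standard is prepared in triplicate, giving one calibration fit per replicate set; `intercept_se()` offers the single-fit alternative |

## What the simulator does and does not emulate

`absorbance_profile()` builds
$y(\nu) = m_\mathrm{mass} \cdot c \cdot \sum_i s_i e^{-(\nu-\nu_i)^2/2w_i^2}
 + \mathrm{drift}(\nu) + \mathrm{matrix}(\nu) + \varepsilon(\nu)$
and the reflectance generator builds the same model in KM units before
inverting to %R, so noise is additive exactly where the calibration is
fitted. It reproduces: strict linearity in concentration, seeded
replicate-to-replicate noise, pellet/cup mass sensitivity, affine baselines,
and excipient bands outside the analytical window. It does **not**
reproduce: non-Gaussian line shapes or apodization effects, particle-size
and packing physics of DRIFTS, humidity bands, detector nonlinearity, or
matrix absorption inside the window. Passing end-to-end tests therefore
demonstrates that the *statistical pipeline* is correct and unbiased under
its stated model, not that the physical method will achieve the same figures
on a given instrument.

The generator's truth record carries two slopes. `slope_analytic` is the
closed-form Gaussian area $s\,w\sqrt{2\pi}$ of the analytical band.
`slope_protocol` is the area per unit concentration that the quantification
protocol actually delivers on a noiseless spectrum: the window truncates the
band and the chord subtracts its endpoint tails, which costs ≈0.5% for the
wide doxorubicin window but ≈30% for the narrow arterolane window
(1690–1630 cm⁻¹ around a 12 cm⁻¹-sd band). Estimator-recovery tests compare
against `slope_protocol`: least squares is unbiased for the slope of the
measurement process as performed, and the truncation is a fixed property of
the method, not an estimation error. Both slopes are themselves checked
against an independent closed-form oracle (truncated Gaussian mass minus
chord term) in the test suite.

## Numerical choices and degenerate inputs

- %T/%R values ≤ 0 or > 100 are rejected on construction and on read —
  never clipped. An epsilon floor before a log or KM transform would
  manufacture signal where the detector reported none.
- Wavenumbers are stored ascending; descending input (the conventional IR
  display direction) is reversed pairwise on construction. Duplicate
  wavenumbers are an error.
- Integration windows are inclusive; a window holding fewer than two grid
  points is an error ("window too narrow for grid").
- JCAMP-DX support covers AFFN `XYDATA`/`XYPOINTS` with `XFACTOR`/`YFACTOR`;
  compressed encodings raise a clear error rather than a misparse.
- The simulator clamps the linear ordinate at zero so %T/%R stay physical;
  with the default background offset the clamp is provably inactive
  (offset = 50 noise sd), keeping the noise model exactly additive and the
  slope estimator unbiased.
- Out-of-range inverse predictions are flagged, not refused: formulation
  assays deliberately use the curve, and refusing would hide that choice.
- All reported tables round to 3 decimals for display; JSON reports keep
  full precision.

## Open design choices

- **Two recovery formulas.** The overall form $100\,C_v/(C_u+C_a)$ is what
  published recovery tables for these assays tabulate; the standard-addition
  form $100\,(C_v-C_u)/C_a$ is the textbook definition and tells a different
  story on the same record (93.0% vs 72.0% on the first bundled arterolane
  row). Both are computed and reported side by side; neither is silently
  "corrected" into the other.
- **Assay concentration.** The simulated formulation assay runs at a nominal
  concentration inside the calibrated range (the middle standard), because
  the purpose of the simulated study is an in-range end-to-end identity
  check. Real protocols that dilute a formulation to a fixed %w/w outside
  the calibrated range are extrapolations the model flags.
- **Intra-day pooling.** A day's repeated sessions are pooled into one
  same-day replicate set before the %RSD; the per-(level, day) breakdown is
  returned alongside.

## Problem sizes

The test suite and the acceptance script use: 450–4000 cm⁻¹ grids at
4 cm⁻¹ (889 points), 5-level calibrations in triplicate, 3×3×3 precision
grids, 3 robustness masses, 5 assay replicates, a 200-draw Monte-Carlo
slope-recovery study at area-noise sd 0.005, and 60 spectrum-level
calibration replications. A full two-mode validation pair runs in a few
seconds on one core.

## Known limitations

- Univariate only: one band, one window. No PLS/PCR multivariate
  calibration, no peak fitting or deconvolution.
- Chord baseline only; rubber-band, asymmetric-least-squares or polynomial
  baselines are out of scope.
- No vendor binary formats (SPC/OPUS), no interferogram processing, no
  atmospheric compensation.
- The DRIFTS physics beyond the KM function — particle size, packing
  density, humidity — is acknowledged but unmodelled; conclusions about
  mode robustness rest on the mass-sensitivity convention stated above.
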