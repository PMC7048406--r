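---
title: "Estimating grassland biomass from satellite NDVI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating grassland biomass from satellite NDVI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassinvert)
```

## The estimation problem

Dry-weight aboveground biomass (AGB, g m⁻²) is the basic currency of
grassland productivity and degradation monitoring, but clipping and drying
quadrats is slow and local. Satellite NDVI covers the landscape but is not
biomass. The bridge built here is the classical two-stage empirical one:

1. relate biomass to *ground* NDVI, measured with a field imaging
   spectrometer over the same 1 × 1 m quadrats that are clipped;
2. relate ground NDVI to *satellite* NDVI at the plot scale, where a
   30 × 30 m plot matches one satellite pixel;
3. compose the two into a single map from satellite NDVI to biomass and
   apply it cell by cell to the NDVI raster.

The two stages are kept separate because they fail for different reasons:
stage 1 carries the biology (how much standing biomass a given canopy
greenness implies), stage 2 carries the sensor physics (bandpass,
atmosphere, scale mismatch between a 0.2 m field footprint and a 30 m
pixel).

## Models

**Ground model.** Four candidate forms for biomass $y$ against ground NDVI
$x$ are fitted and compared: linear $y = ax + b$, logarithmic
$y = a\ln x + b$, power $y = ax^b$, exponential $y = ae^{bx}$. The power
and exponential forms are fitted by log-linearization (OLS of $\ln y$ on
$\ln x$ or $x$), the convention behind published trendline equations; it is
deterministic and reproducible from printed coefficients. An optional
`refine = TRUE` polishes these with `stats::nls`, which weights large
residuals more heavily on the original scale; it is off by default because
the log-scale fit is the convention the comparison targets assume.

Model ranking uses $R^2 = 1 - SS_{res}/SS_{tot}$ computed on the
**original** biomass scale from back-transformed predictions (so all four
families are compared on the same footing), with the held-out standard
error as tie-break. Because published equations of this form do not always
state which scale their $R^2$ used, the log-scale $R^2$ of the linearized
fit is also reported (`r2_fit_scale`).

**Cross-calibration.** Plot-mean ground NDVI is regressed on satellite
NDVI, $SOC = c\,TM + d$, by OLS. The direction is fixed — ground on
satellite — because the composition requires a map *from* the satellite
observable *to* the ground model's argument; inverse or orthogonal
regression would not compose. Plot-mean ground NDVI is the mean of the
plot's quadrat NDVIs, the only ground data available at plot scale.

**Composite model.** Substitution gives
$AGB(t) = a\,e^{b(ct + d)}$. The object stores the four parent constants
(provenance), not the reduced two-constant form $(ae^{bd})e^{(bc)t}$; both
evaluations are tested to agree to 1e-12 relative.

**Accuracy statistics.** $SE = \sqrt{\sum_i (y_i - y_i')^2 / n}$ in g m⁻²
(the root is forced by the unit) and $MEC = 100\sum_i |y_i - y_i'|/y_i / n$
in percent. One implementation serves both the family comparison and the
final validation, so the two stages are bit-comparable.

## NDVI from hyperspectral reflectance

Raw spectrometer counts become reflectance via a reference panel and dark
current: $\rho = (target - dark)/(panel - dark) \times \rho_{panel}$.
Reflectance is capped at 1.2 with a warning rather than rejected — field
panels routinely produce slight overshoots near specular targets.

Broadband RED (630–680 nm) and NIR (845–885 nm) reflectances are the
**unweighted means** of channels whose centers fall in the window,
endpoints inclusive. With 2.3 nm channel spacing the windows contain ~22
and ~18 channels, so unweighted averaging, trapezoidal integration and
spectral-response weighting agree to well under 1%; the simplest convention
is used and tested for grid-resolution stability (2.3 nm vs 1 nm grids
agree to < 0.005).

Quadrat NDVI is the **mean of per-spectrum NDVIs**, not the NDVI of the
mean spectrum. The two differ for heterogeneous quadrats (NDVI is a ratio);
a fixed convention is declared and tested with an explicit two-spectrum
counterexample. Plot NDVI is the arithmetic mean of quadrat NDVIs.

## The synthetic campaign

The generator replaces a field campaign while preserving exactly the
statistical structure the analysis assumes; its defaults are the study
conditions used throughout the tests:

* **Layout:** 39 plots, 173 quadrats (4–5 per plot; 173/39 is not an
  integer, so the first 17 plots carry 5 — the true per-plot layout of such
  campaigns varies and only the totals matter downstream), splits 153/20
  and 115/38.
* **Spectra:** linear mixing of two idealized endmembers on the 400–1000 nm
  grid at 2.3 nm (the resolution of the field instrument emulated):
  vegetation with a logistic red edge at 720 nm, a small 550 nm green bump
  and an NIR plateau (NDVI ≈ 0.89); soil as a gently rising line
  (NDVI ≈ 0.11). Only the band-window means matter downstream. Gaussian
  channel noise, s.d. 0.005 reflectance — the repeatability of a
  well-operated field spectrometer.
* **Cover:** plot-level vegetation cover uniform on [0.15, 0.95], quadrat
  cover Gaussian around its plot mean with s.d. 0.06. This puts quadrat
  ground NDVI in roughly [0.27, 0.85]: a realistic semi-arid grassland
  range that also keeps the implied satellite NDVI $(SOC - d)/c$ inside
  [−1, 1] under the default calibration constants.
* **Biomass:** $AGB = a e^{b \cdot SOC}(1 + \varepsilon)$,
  $\varepsilon \sim N(0, 0.2)$, floored at 0.01 g m⁻². The noise is
  multiplicative (constant CV) because field biomass scatter grows with the
  mean; additive noise of useful size would produce negative biomass at low
  NDVI. Defaults $a = 12.523$, $b = 3.370$ give 30–220 g m⁻² over the NDVI
  range — typical steppe values.
* **Satellite NDVI:** $TM = (\overline{SOC} - d)/c + \eta$,
  $\eta \sim N(0, 0.05)$, clipped to [−1, 1], with defaults $c = 0.462$,
  $d = 0.413$; 0.05 is a moderate cross-sensor discrepancy after
  atmospheric correction.
* **Raster:** 50 × 50 cells of 30 m, nodata −9999, one distinct pixel per
  plot carrying that plot's satellite NDVI; quadrat coordinates are
  jittered inside their plot's pixel. Real scenes are far larger, but the
  inversion is cellwise, so nothing is lost at desk scale.

Identical config + seed reproduces every table and raster byte for byte;
the generator saves and restores the caller's RNG state.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: canopy radiative transfer (no PROSAIL-class
bidirectional effects), atmospheric residuals, geolocation error between
plots and pixels, mixed pixels at plot edges, vegetation-type differences
in the biomass–NDVI law, and any spatial autocorrelation of cover beyond
the plot level. The recovery tests certify the *pipeline*, not the field
applicability of the exponential law.

## Raster handling

Rasters are minimal north-up grids with square cells, an affine
geotransform (top-left origin, cell size) and an exact nodata sentinel.
Cells are half-open: $x \in [left, right)$, $y \in (bottom, top]$, so
every point belongs to exactly one cell and point extraction is a floor of
the inverse geotransform — matching the "value of the containing pixel"
convention, with no interpolation. Points outside the bounds or on nodata
pixels yield per-point statuses, never a crash.

On disk the package uses the ESRI ASCII grid (`.asc`): a plain-text,
GIS-standard single-band format carrying the full geotransform and nodata
tag. Values are written with 17 significant digits, so write–read round
trips reproduce doubles and the geotransform bit for bit.

Saturation: cells whose predicted biomass exceeds the threshold (default
250 g m⁻², where NDVI sensitivity is lost in dense canopy) are flagged in
a mask but keep their values — flagging leaves the censoring decision to
the analyst. Note that under the default composite constants the
prediction at NDVI = 1 is ≈ 239 g m⁻², so the default threshold is only
reachable with other calibrations; the flag is exercised in tests at a
lower threshold.

## Numerical and degenerate-input choices

* OLS goes through `stats::lm`; tests check all four families against a
  hand-written normal-equations oracle to 1e-10 relative on small random
  instances.
* Family selection: maximum training $R^2$, ties (within 1e-12) broken by
  minimum held-out SE. Families that cannot be fitted (non-positive values
  where a log is needed) are recorded as failed and excluded, not fatal.
* `mec()` refuses zero measured values rather than silently skipping them;
  validation drops pairs with *missing predictions* pairwise and reports
  the count.
* Degenerate regressors error early with a named cause: zero-variance
  satellite NDVI, panel counts not exceeding dark counts (the offending
  channel is named), a zero cross-calibration slope in the generator.
* NDVI at $RED + NIR = 0$ is an error, never a silent 0.

## Problem sizes in the test suite

The suite certifies: exact metric arithmetic on toy vectors; oracle
equivalence on 30 random instances of $n \le 10$; a zero-noise round trip
of the full pipeline recovering the generator constants to six significant
digits; a 200-campaign sweep at the study scale (39 plots / 173 quadrats,
20% biomass CV) checking that the exponential family is selected in at
least 80% of runs and that the median relative error of its recovered
coefficients stays under 10%; and the raster contracts (cellwise equality
with scalar evaluation to 1e-12, nodata conservation, bit-stable file
round trips). These sizes were chosen to estimate the selection rate and
median errors stably; the sweep runs in a few seconds.

## Known limitations

* The exponential ground model is empirical; out-of-range extrapolation
  (NDVI beyond the calibrated span) is not guarded beyond the [−1, 1]
  domain check.
* No uncertainty propagation through the composed model — SE/MEC at
  held-out points are the only accuracy statements.
* One satellite sensor, one date: no multi-scene mosaics, reprojection, or
  cloud masking; input rasters are assumed analysis-ready.
* Plot-mean ground NDVI is a quadrat mean, not a full-plot average; with
  4–5 quadrats per plot this adds sampling noise to the cross-calibration
  that the generator reproduces but cannot remove.
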