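---
title: "Methods: spectral indices, water budget and multivariate calibration for deficit-irrigated wheat"
author: "specyield maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral indices, water budget and multivariate calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specyield)
```

## The problem

Spring wheat grown under limited water supply responds jointly to the
irrigation rate and to the plant density: yield and biomass rise with
water, are concave in density, and the best density moves downward as
the deficit grows. Canopy hyperspectral reflectance (350--2500 nm)
carries enough information about leaf area, pigments and canopy water to
estimate the season's biophysical outcomes — green leaf area (GLA,
cm^2^ plant^-1^), aboveground dry weight (TDW, g m^-2^), grain yield
(GY, g m^-2^) and water use efficiency (WUE, g m^-2^ mm^-1^) — without
destructive sampling. `specyield` implements the full analysis chain
for such experiments: index computation, exhaustive two-band index
discovery, treatment-subset regression, a water budget with the yield
response factor, and full-spectrum PLSR/SVR calibration, together with
a synthetic-experiment generator that makes every stage testable end to
end.

## Data model

Spectra live in a `SpectralDataset`, a `SummarizedExperiment` whose
rows are wavelengths on a shared `WavelengthGrid` (canonically
350--2500 nm at 1 nm, 2151 bands, the grid to which field
spectroradiometers resample) and whose columns are experimental units
keyed by season, irrigation rate (a fraction of estimated crop
evapotranspiration: 1.00, 0.75, 0.50), plant density (seeds m^-2^) and
replicate. The wide-CSV interchange layout has a `wavelength_nm`
column followed by one column per sample named
`S<season>_I<rate>_D<density>_R<rep>`; an XLSX reader with a
configurable header-mapping hook accepts spreadsheet variants of the
same layout. Reflectance above 1 is accepted with a warning (specular
and panel effects occur in the field); negative values are rejected.

## Spectral indices

`builtinDefinitions()` returns the twenty index formulas used
throughout: twelve two-band normalized difference indices
(`(R1 - R2)/(R1 + R2)`) on band pairs selected from contour-map
hotspots, plus eight published indices (MSI, SRWI, NWI-3, NDVI, NDMI,
NMDI, OSAVI, MTVI). Two published formulas required an editorial
decision:

* **NMDI.** The printed source formula has typographically ambiguous
  grouping that is inconsistent with the formula's own literature
  reference. The default is the literature form
  `(R860 - (R1640 - R2130)) / (R860 + (R1640 - R2130))`; the printed
  variant (plus sign in the denominator's SWIR term) is available via
  `nmdiAsPrinted = TRUE`.
* **MTVI.** The printed bracket is unbalanced; the implementation uses
  the structure of the cited literature,
  `1.2 [1.2 (R800 - R550) - 2.5 (R670 - R550)]`.

Bands are looked up exactly on the integer-nm grid — no
nearest-neighbour snapping — because the grid is canonical after
resampling. Tests assert the scale-invariance split: normalized
differences, simple ratios and NMDI are invariant under uniform
rescaling of the spectrum, OSAVI and MTVI deliberately are not.

## Exhaustive band search

`ndiR2Map()` regresses a trait on NDI(λ1, λ2) for every band pair of a
stepped lattice and stores the coefficient of determination. With one
regressor the OLS R² equals the squared Pearson correlation, which is
what is computed (one band row at a time, vectorized across the other
band and all samples). Cells with a constant or undefined index are
masked rather than dropped, so the lattice geometry is stable and
hotspot connectivity is well defined; the diagonal is always masked
(NDI(λ, λ) ≡ 0). Swapping bands flips the regressor's sign, so the map
is exactly symmetric — the implementation computes both triangles and
the test suite asserts bitwise symmetry. The default lattice step is
4 nm (538 bands, ≈145k pairs), a desk-scale compromise; 1 nm gives the
exhaustive map. `hotspotExtract()` labels 4-connected supra-threshold
regions via the graph-components machinery of igraph and ranks them by
peak R². The hotspot threshold has no canonical published value and is
a free argument.

## Treatment-subset regressions

`subsetRegressions()` reproduces the five reporting schemes of
index--trait tables on the crossed design. All schemes start from
replicate means per season × rate × density cell (30 records on the
reference design): within each irrigation rate (n = 10), within each
density (n = 6), density-averaged within rate × season (n = 6),
rate-averaged within density × season (n = 10), and all records pooled
(n = 30). Means are taken over *derived* quantities — index values and
traits — not over spectra, because index nonlinearity makes the order
matter and the tables are built from per-plot indices. R² is the plain
(not adjusted) squared correlation; p-values are two-sided from the t
statistic with n − 2 df; stars mark 0.05/0.01/0.001. No
multiple-testing correction is applied, matching the reporting practice
the tables emulate, which is why the permutation-null calibration test
(false-star rate 5% at α = 0.05) matters.

## Water budget

`penmanMonteithEto()` is the standard FAO-56 reference form. The
generator's meteorology is calibrated to the site's monthly climate
normals (December--April means 16.4, 14.6, 17.3, 21.5, 26.9 °C; arid,
low humidity), with the psychrometric constant at 400 m elevation.
Seasonal crop ET of a plan is Σ(ETo · Kc) scaled by the deficit factor,
so deficit plans receive exactly 75%/50% of the full plan's water; Kc
values are inputs (published adjusted values are not available).
Seasonal actual ET uses the water balance
`ET = ETc + P + Cr − R − D + ΔS` with two conventions resolved here:

* **ΔS sign.** The printed form is sign-ambiguous ("± ΔS"); we define
  ΔS = storage(sowing) − storage(harvest) and add it, so that profile
  depletion adds to seasonal ET, the usual water-balance reading.
* **Deep percolation.** Operationalized as a per-event capacity
  overflow: `max(0, pre-event storage + applied − FC capacity)` over
  the 0.9 m root zone.

`kySingle()`/`kyPooled()` implement the yield response factor: the
ratio (or through-origin regression slope, the default, since the
formulation ties zero deficit to zero decrease) of relative yield
decrease `1 − GYa/GYm` to relative ET deficit `1 − ETa/ETm`. ky is
reported at two decimals, full precision kept internally. The package
ships the twenty published per-treatment ratio pairs as input data
(`publishedKyInputs()`); fifteen of the printed ky cells agree with
their own printed ratios to ±0.005 and are reproduced exactly at report
precision, the other five differ only through the 3-decimal rounding of
the printed inputs (one is a gross misprint, 1.13 where the ratio gives
1.23) and are treated as documented exceptions, not test failures.

## Multivariate calibration

`fitCalibration()` calibrates a trait on the full 350--2500 nm
spectrum with PLSR (PLS1/NIPALS, authored here) or ε-insensitive SVR
(e1071). Candidate settings — latent factors 1..min(20, n − 2) for
PLSR, a small cost grid with a linear kernel for SVR — are scored by
leave-one-out RMSECV and the minimizer is selected, with ties at
numerical tolerance (10^-8^ · sd(y)) resolved toward the simpler
setting; on noise-free low-rank data this picks the true rank instead
of drifting into numerically indistinguishable larger models. The only
default preprocessing is mean-centering of X and y: the minimal
canonical PLSR choice, configurable. The linear kernel is the
conservative SVR default for n ≪ p spectra. Before cross-validation
the spectra are rotated into their row space by SVD; for centered
linear models this is exact (identical fits and predictions) and makes
leave-one-out over 2151 bands cheap. The choices of leave-one-out CV
and the factor cap reflect the small-n/large-p regime of such
calibrations. Validation (`validateCalibration()`,
`subsetValidationSuite()`) never refits: the frozen model predicts each
subset (per rate, per density, per season; 3 + 5 + 2 = 10 reports), and
the report carries adjusted R² (`1 − (1 − R²)(n − 1)/(n − 2)`), RMSE,
the slope/intercept of predictions against observations, and both
ranges. An independent PLS implementation (mixOmics) serves as a
cross-check oracle in the test suite, never as the implementation.

## The synthetic experiment

`generateExperiment()` produces the full reference design (2 seasons ×
3 rates × 5 densities × 3 replicates = 90 plots). Its defaults *are*
the study conditions and are not tuned per analysis:

* **Water.** Full-irrigation seasonal totals 558/555 mm with 38/45 mm
  sowing applications (published values); effective rain 45/40 mm and
  deep percolation 25 mm · rate are chosen so that the relative ET
  deficits of the 0.75 and 0.50 treatments land near 0.22 and 0.43, as
  the published per-treatment ratios show. The storage change averages
  8 mm (sd 2 mm across plots).
* **Yield.** `GY = GYpeak · (1 − ky·deficit) · g(d, w)` with ky = 1.3
  (the published pooled values are 1.32/1.28), peak 950/905 g m^-2^,
  and a concave density response `g` (curvature 0.5 over a 400
  seeds m^-2^ scale) whose optimum shifts from 350 seeds m^-2^ at full
  irrigation downward by 150 · (1 − rate) — the published pattern of
  the best density moving from D3 toward D2 under deficit. Linearity
  in ET makes the implied basal ET equal ETm(ky − 1)/ky
  (`generatorBasalEt()`), which the production-function recovery tests
  target. TDW is 2.4 × the yield surface; GLA divides canopy leaf area
  by density.
* **Spectra.** Each plot's latent state (cover, LAI, chlorophyll and
  water proxies) drives an analytic two-endmember mixture: a bright
  smooth soil curve and a vegetation endmember with a green peak at
  550 nm, chlorophyll-scaled absorption at 670 nm, an NIR plateau
  saturating as 1 − exp(−0.6·LAI) and water-scaled troughs at 1450 and
  1940 nm, then multiplicative noise (sd 0.01) and clamping to [0, 1].
  These are deliberately piecewise-smooth analytic shapes, not
  radiative transfer: only the qualitative VIS↓/NIR↑/SWIR-trough
  structure matters for testing the chain.
* **Noise.** Plot-level latent variation (CV 0.02) is visible in the
  spectra; trait measurement noise (CV 0.05) is not. The per-plot
  variance components of the original field experiment were never
  published, so these are free parameters chosen as realistic for
  managed field trials, and the noise ceiling used in the recovery
  tests is computed from the generator's own noise-free surface.
* **Determinism.** Every record's draws come from a stream keyed by
  (seed, record index), so equal seeds are bit-identical and
  subsetting the design (e.g. one season) reproduces the same values.

What passing tests on this generator do show: the chain's formulas,
selection rules and reporting layouts are correct, and signal planted
with realistic structure is recovered at the expected accuracy. What
they do not show: performance on real canopies with soil
heterogeneity, row geometry, instrument jump artifacts or atmospheric
effects, none of which the generator emulates.

## Numerical choices and degenerate inputs

Constant regressors yield flagged-undefined results rather than NaNs;
constant traits mask whole R² maps; a zero ET deficit flags ky
undefined; reference radiance ≤ 0 names the offending band;
water-balance ET ≤ 0 is an error. The PLS path stops when the residual
covariance norm falls below 10^-10^ of its first-component value
(rank exhausted). Map cells are declared constant below an index
standard deviation of ~10^-12^. File round-trips write 17 significant
digits so reading back is bit-identical.

## Problem sizes

The shipped tests run the full 2151-band reference design for the
synthetic chain, 20-band × 10-sample instances against brute-force
oracles, 50-seed permutation nulls, and 25-seed noise-ceiling recovery
for PLSR — sizes chosen so the whole suite completes in about a minute
on a laptop while keeping every estimate's Monte-Carlo error far below
its acceptance band. The band-search default step of 4 nm (and larger
steps in orchestrated runs) trades lattice resolution for time; the
1 nm exhaustive map is available wherever a step argument is taken.

## Known limitations

The generator's treatment effects are smooth and low-dimensional, so
multivariate models approach their noise ceiling more easily than on
real data. Soil moisture dynamics between irrigation events are not
simulated (percolation is per-event overflow), Kc curves are inputs
rather than estimated, and the XLSX reader requires the wide layout up
to a header mapping. The pooled-ky free-intercept mode exists because
published seasonal regressions may include an intercept; whether they
did is not stated in the sources this package follows.
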