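---
title: "Methods: three-dimensional SOC stock mapping with a mattic-epipedon depth function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-dimensional SOC stock mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soc3d)
```

## The problem

Alpine grassland soils of the Tibetan Plateau store large amounts of organic
carbon, much of it in the *mattic epipedon* — a dense, mat-like surface
horizon of living and dead roots mixed with organic soil material, diagnostic
of alpine meadow. Ordinary depth models for soil organic carbon (SOC) assume
monotone decline from the surface; under a root mat that assumption
misallocates carbon, because content is roughly constant through the mat and
only decays below it. `soc3d` implements a complete pipeline that takes this
horizon seriously: profile preparation, a mat-aware depth function, spatial
prediction of its parameters from environmental covariates, closed-form depth
integration into stock maps, and a validation suite — plus a seeded synthetic
generator so every stage can be tested without field data.

## The depth function

Volumetric SOC content (kg m⁻³) at depth $z$ (m, positive downward) is
modelled per profile as

$$
C_v(z) \;=\;
\begin{cases}
C_a, & z \le d_{mat} \\[4pt]
C_a \, e^{-k\,(z - d_{mat})}, & z > d_{mat},
\end{cases}
$$

with four parameters: mattic occurrence (categorical), mattic depth
$d_{mat}$ (m; 0 for profiles without the mat), surface content $C_a$
(kg m⁻³) and decay rate $k$ (m⁻¹). Anchoring the exponential at $d_{mat}$
rather than at the surface is a deliberate choice: it is the only form under
which the mat content equals the surface content and the function is
continuous at the mat base; an un-shifted exponential would jump there.
Profiles without a mat reduce to the ordinary exponential decline.

The stock over a depth layer $[a, b]$ has a closed form — the plateau
contributes $C_a$ times its overlap with $[0, d_{mat}]$ and the tail
integrates analytically — so stock maps are computed exactly, never by
summing thin slices. Slices (`discretize_profile()`, 1 cm by default) exist
only for visualising vertical sections.

## Profile preparation

Laboratory SOC is reported on a mass basis (g C per kg fine earth); the
depth function needs volume basis. The conversion is
$C_v = C_m \cdot \rho_b \cdot (1 - G)$ with bulk density $\rho_b$ (g cm⁻³)
and the volume fraction $G$ of rock fragments > 2 mm. $G$ is a *fraction*
throughout, not a percent. Where bulk density was not measured it is filled
by a pedo-transfer function $\rho_b = a_0 + a_1 e^{-a_2 \cdot C_m}$, a
standard monotone-decreasing family; the defaults
($a_0 = 0.5$, $a_1 = 0.9$ g cm⁻³, $a_2 = 0.008$ per g kg⁻¹) give
1.40 g cm⁻³ for carbon-free mineral soil and approach 0.5 g cm⁻³ in
root-mat material, and are configurable so a locally calibrated PTF can be
swapped in. Measured densities always take precedence.

Mattic occurrence itself is treated as field truth (expert identification);
`check_mattic_criteria()` only reports advisory flags on the two criteria
measurable from the data model (thickness > 5 cm; surface bulk density
0.5–1.1 g cm⁻³) and never overrides the flag.

## Fitting

Each genetic horizon contributes one observation located at its midpoint
depth — the simplest unbiased depth support when the true within-horizon
distribution is unknown. With occurrence and $d_{mat}$ fixed from the field
record, the free parameters $(C_a, k)$ minimise the sum of squared errors,
with within-mat observations fitted by the constant $C_a$ so that both
segments share it. The bounded nonlinear least-squares problem
($k \in (10^{-3}, 50)$, $C_a \in (10^{-3}, 500)$) is solved by variable
projection: for fixed $k$ the optimal $C_a$ is a linear coefficient, leaving
a one-dimensional profile objective in $k$ that is bracketed on a 257-point
log-spaced grid and polished with Brent's method (`optimize`, tolerance
$10^{-12}$ on $\log k$). This is deterministic, needs no starting values and
reproduces the two-point closed form $k = \ln(v_1/v_2)/(z_2 - z_1)$ exactly
when only two sub-mat observations exist. Identifiability requires at least
two distinct depths below the mat; mat-only profiles are rejected ($k$
undetermined). $R^2$ is computed about the mean of the observed contents.

## Spatial prediction

The four parameters are carried across space by four random forests on an
18-layer covariate stack (terrain attributes consumed as prepared rasters,
climate, Landsat-like bands and NDVI, and cell-center coordinate layers):

* occurrence — classification forest, `mtry = 4`;
* $\log d_{mat}$, $\log C_a$, $\log k$ — regression forests, `mtry = 6`,
  natural-log targets back-transformed with `exp` (no smearing correction);

all with 1000 trees. The mattic-depth regressor is trained only on
mat-bearing sites, since the depth is undefined elsewhere and its log does
not exist at zero. The forests are supplied by `ranger`, run single-threaded
with an explicit seed so training and prediction are bit-reproducible; the
occurrence model is a probability forest whose majority vote breaks exact
ties toward "no mattic" (conservative, and rare at 1000 trees). Out-of-bag
(OOB) evaluation reports the misclassification rate of OOB votes for the
classifier and OOB mean square error *on the log scale* for the regressors;
`repeat_oob()` summarises both over re-seeded runs (seeds
$s, s+1, \dots$) with min, quartiles, mean, median, max and SD. Variable
importance is the permutation measure computed at training; for the
probability forest it is on the Brier scale, which preserves ranking.

Prediction over a stack applies the models pixelwise; a pixel missing in any
covariate layer is masked everywhere, and predicted $d_{mat}$ is forced to 0
where occurrence is negative. Back-transformed $C_a$ and $k$ are positive by
construction.

## Stocks, areas and sections

`map_stock()` evaluates the closed-form integral per pixel for any layer,
including the per-pixel mattic layer $[0, d_{mat}]$; `total_stock()`
multiplies by the pixel area (cell size squared) and reports totals in Tg
($10^9$ kg) and means in kg m⁻²; `relative_stock_report()` expresses layer
totals as percentages of a reference layer (conventionally 0–100 cm);
`mattic_area()` counts mat pixels times cell area. Soil is assumed at least
1 m deep at every mapped pixel — integration always runs to the requested
depth; a bedrock-depth raster, if available, can be applied by truncating the
integration interval upstream. Mass conservation (adjacent layers summing to
the whole) holds to floating-point accuracy because the integrals are exact.

## Validation

Three indices compare predicted against observed stocks: mean error
(`predicted − observed`, so negative means under-prediction), RMSE, and
Lin's concordance correlation coefficient
$\mathrm{LCCC} = 2 r s_p s_o / (s_p^2 + s_o^2 + (\bar p - \bar o)^2)$ with
population ($1/n$) variances — the agreement-with-the-45°-line index, which
penalises location and scale shifts that Pearson correlation ignores.

*Internal* validation compares the stock map at each calibration site's
pixel against the integral of that site's own fitted depth function; being
in-sample it overstates accuracy and is reported alongside *independent*
validation, which uses profiles sampled at a contiguous 5-cm interval and
sums `content × 0.05 m` increments — a model-free observed stock. The
default layer for both is 0–100 cm, with any layer available per call.
`repeat_validation()` re-runs the whole train–map–validate procedure across
seeds and summarises each index with the seven statistics; re-seeded forest
training is the only stochastic component. `residual_semivariogram()`
implements the classical Matheron estimator on validation residuals; a flat
variogram means no spatial structure is left for kriging to exploit.

## The synthetic generator

The generator defines the study conditions under which the pipeline is
benchmarked: a 200 × 200 grid of 90-m cells, 96 calibration pedons sampled
by genetic horizon, and 3 independent pedons at 5-cm intervals. Covariates
are standardized Gaussian random fields (white noise under a separable
Gaussian kernel, radius 12 pixels, reflection padding) with the field's
characteristic couplings: a 6 °C km⁻¹ elevation lapse on temperature
(MAT–elevation correlation below −0.9), precipitation declining with
elevation, and red/NIR bands back-solved from the NDVI field so
`compute_ndvi()` reproduces it identically. Latent parameter fields follow
logistic and log-linear links on standardized NDVI, MAT and elevation, with
coefficients chosen once to mirror survey magnitudes for these soils —
mattic prevalence near 40 % of sites, mat depths 6–30 cm around a 15-cm
mean, surface contents of 25–40 kg m⁻³ under productive meadow against
10–15 kg m⁻³ in steppe, decay rates near 2 m⁻¹ — and clamped to those
physical ranges.

Horizon observations are the *average* of the true function over the horizon
(integral over thickness), not the midpoint value, times mean-one lognormal
noise with a 10 % coefficient of variation. Fitting at midpoints therefore
faces a small, realistic model discrepancy: recovery tests exercise
robustness rather than inverting the generator's own construction. Bulk
density and gravel increase with depth and the mass-basis content is
back-computed so the conversion chain is exercised end to end. What the
generator does *not* emulate: geostatistically calibrated variograms of a
real landscape, purposive (non-uniform) site selection, Landsat radiometry,
bedrock shallower than 1 m, and mattic misidentification (the flag-error
rate defaults to 0). Passing recovery tests therefore demonstrates the
pipeline's internal consistency under known truth, not survey-grade accuracy
on real terrain.

All draws descend from one master seed through documented per-stage
sub-seeds, so a scenario regenerates bit-exactly, and the full
simulate → fit → train → predict → validate chain is reproducible
file-for-file.

## Numerical choices and degenerate inputs

* Depths in meters, positive downward; horizons half-open $[top, bottom)$;
  row 1 of every raster is the northernmost; values are cell centers.
* Horizon intervals must be non-overlapping and ordered; inverted depths,
  duplicate keys and out-of-range gravel or density values are rejected with
  the offending row or site named.
* A mattic flag requires a mat depth > 0.05 m (thinner mats do not qualify).
* Fits with all observations inside the mat, or fewer than two distinct
  sub-mat depths, raise identifiability errors rather than returning a
  boundary value.
* `lccc()` is undefined when both vectors are constant and errors; with a
  single pair it errors (`n ≥ 2`).
* Stock integration validates $0 \le z_{top} < z_{bottom}$; zero-length
  layers are rejected.
* The ESRI ASCII raster dialect carries no CRS; a tag is attached on read.
  Nearest-neighbour resampling serves categorical layers, bilinear (with
  edge clamping and NA propagation) continuous ones; bilinear is also the
  assumption for coarse climate layers brought to the common grid.

## Problem sizes used in the test suite

Module tests run on 30–60-pixel-square grids with 25–60 sites so the whole
suite stays fast; the end-to-end benchmark runs the full default scenario
(200 × 200 pixels, 96 + 3 sites, 10 master seeds), where the mapped
0–100 cm total lands within 15 % of the analytic truth and independent
concordance clears 0.5 in at least 8 of 10 seeds, with internal concordance
exceeding independent — the in-sample optimism ordering — in at least 8 of
10. The quadrature cross-check of the closed-form integral is run against a
trapezoid oracle with a node at the mat base; at the 10⁻⁴ m step the
oracle's own discretization error ($\approx k^2 h^2/12$) caps attainable
agreement, so the 10⁻⁸ comparison uses decay rates up to 3.4 m⁻¹ and a
finer-step oracle covers steeper profiles at the same tolerance.

## Known limitations

* No uncertainty quantification: the pipeline maps point predictions only.
* The naive `exp` back-transform of log-scale forest predictions is slightly
  biased low for the mean; no smearing correction is applied.
* Internal validation shares pixels with training and is optimistic by
  construction; with only three independent profiles the independent indices
  are themselves high-variance.
* Terrain derivatives are consumed, not computed; supplying them on a
  different grid requires resampling first.
* The mattic-depth model never sees non-mat sites, so its errors interact
  with classifier errors at mat boundaries.
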