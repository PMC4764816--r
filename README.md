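# soc3d

Three-dimensional soil organic carbon (SOC) stock mapping for alpine
grassland soils.

## The problem

Alpine meadows of the Tibetan Plateau carry a **mattic epipedon** — a dense,
mat-like surface horizon of living and dead roots with very high organic
carbon. Standard SOC depth models assume content declines monotonically from
the surface, which misplaces carbon wherever such a mat exists. `soc3d` is
for soil scientists and carbon-cycle modellers who need wall-to-wall,
depth-resolved SOC stock estimates from sparse soil profiles plus
environmental covariate rasters, with the root mat modelled explicitly.

## The model

Volumetric SOC content at depth *z* (m) is a step-wise exponential with a
surface plateau:

```
C_v(z) = C_a                         for z ≤ d_mat
C_v(z) = C_a · exp(−k · (z − d_mat)) for z > d_mat
```

Four parameters per site or pixel: mattic occurrence, mat depth `d_mat` (m,
0 where absent), surface content `C_a` (kg m⁻³, equal to the mat content
where a mat exists — the form is continuous at the mat base), and decay rate
`k` (m⁻¹). The pipeline:

1. **Profile prep** — read per-horizon pedon tables, fill missing bulk
   density with a pedo-transfer function `BD = a0 + a1·exp(−a2·SOC)`, and
   convert mass- to volume-basis content with gravel correction
   `C_v = C_m · BD · (1 − G)`.
2. **Fitting** — bounded nonlinear least squares of `(C_a, k)` per profile
   at horizon midpoints, with occurrence and `d_mat` fixed from the field
   record (solved by deterministic variable projection).
3. **Spatial prediction** — four random forests (occurrence classifier,
   `mtry = 4`; log-target regressors for `d_mat`, `C_a`, `k`, `mtry = 6`;
   1000 trees) on an 18-layer covariate stack, with out-of-bag error
   summaries over repeated seeded runs and permutation importance.
4. **Mapping** — closed-form depth integration per pixel into stock maps
   for any layer (0–30, 0–50, 0–100 cm, or the per-pixel mattic layer),
   area totals in Tg, mattic area in km², and 1-cm vertical sections.
5. **Validation** — mean error, RMSE and Lin's concordance correlation
   coefficient on training sites (in-sample) and on independent pedons
   sampled at 5-cm intervals, plus a residual semivariogram check.
6. **Synthetic data** — a fully seeded generator (smooth covariate fields,
   logistic/log-linear parameter links, noisy horizon sampling) so the whole
   pipeline is testable against known truth.

## Worked example

```r
library(soc3d)

# a mat-covered profile: 41.56 kg/m^3 through an 18-cm mat, decaying below
p <- soc_params(c_a = 41.56, k = 2.31, has_mattic = TRUE, d_mat = 0.18)
evaluate_soc(p, 0.95)    # content at 95 cm
integrate_stock(p, 0, 1) # stock over the top meter

# a complete synthetic survey: simulate, fit, train, map, validate
cfg <- sim_config(n_rows = 60, n_cols = 60, n_calibration = 60, seed = 42)
b   <- simulate_soc_scenario(cfg)
pl  <- run_soc_pipeline(b$calibration, b$stack, b$independent, rf_config(seed = 42))
pl
```

prints

```
<soc_params> c_a = 41.560 kg/m^3, k = 2.3100 1/m, mattic to 0.180 m
content at 0.95 m: 7.02 kg/m^3
stock 0-1 m: 22.77 kg/m^2

<soc_pipeline>
  60 fitted pedons (mean R^2 0.981); mattic area 14.1 km^2
# A tibble: 4 × 4
  layer    mean_kg_m2 total_Tg relative_pct
  <chr>         <dbl>    <dbl>        <dbl>
1 mattic         1.97   0.0574         20.0
2 0-30 cm        4.97   0.145          50.5
3 0-50 cm        7.11   0.207          72.3
4 0-100 cm       9.82   0.286         100
# A tibble: 2 × 5
      n      me  rmse  lccc dataset
  <int>   <dbl> <dbl> <dbl> <chr>
1    60 -0.0959  1.20 0.972 training
2     3 -1.07    1.12 0.205 independent
```

Reading this: depth functions explain 98 % of horizon-level variance on
average; the mapped 0–100 cm total of 0.286 Tg compares to the generator's
analytic truth of 0.291 Tg (a 2 % recovery error on this 60 × 60 scene); the
mattic layer holds 20 % of the 0–1 m stock; and internal (in-sample)
concordance of 0.97 far exceeds the independent value — expected, since
independent validation here rests on just three profiles. `tidy(pl)` returns
the layer table, `glance(pl)` a one-row summary, and
`autoplot(pl$stocks$l0100)` the stock map.

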