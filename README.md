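# gwrshift

Does the ability of **water** and **energy** to explain species richness
shift with latitude?  Water–energy dynamics theory predicts that richness
gradients are water-limited at low latitudes and energy-limited at high
latitudes.  `gwrshift` implements a complete, reproducible pipeline for
testing this prediction on a gridded richness dataset — the kind of
1°×1° cell table used for continental richness gradients of megathermal
taxa such as American palms — using *geographically weighted regression*
(GWR) to quantify the explanatory power of water and energy **locally**,
and then testing how those local quantities change with absolute
latitude.

The package is aimed at macroecologists and spatial statisticians who
want the full chain — local modelling, information-theoretic model
selection, variation partitioning, and autocorrelation-aware trend
tests — as tested R functions rather than a GUI workflow.

## The method

For every grid cell *i*, GWR fits a weighted least-squares regression of
richness on climate, weighting cell *j* by a fixed spatial kernel
evaluated at the great-circle distance d<sub>ij</sub>:

* **bi-square**: w = (1 − (d/b)²)² for d < b, else 0;
* **moving window**: w = 1 for d ≤ b, else 0;

with bandwidths b = 1200 and 1800 km.  Candidate predictors form a
**water** set {AP, MPDM, WD} and an **energy** set {MAT, MTCM, PET},
where WD = PET − AET is a drought index.  Within each set, all 7
subsets of 1–3 variables are ranked by the GWR small-sample corrected
AIC,

AICc = 2n ln σ̂ + n ln 2π + n (n + tr S) / (n − 2 − tr S),

with tr S the effective number of parameters (hat-matrix trace); the
identical formula with tr S = p + 1 gives a like-for-like global-OLS
AICc, so AICc(OLS) − AICc(GWR) measures spatial non-stationarity.

Per cell, the local R² of the best water model (R_w), best energy model
(R_e) and their union (R_t) are split by variation partitioning into
**pure water** R_pw = R_t − R_e, **pure energy** R_pe = R_t − R_w and a
shared fraction.  Each fraction is then regressed on absolute latitude
per hemisphere — by OLS and by a maximum-likelihood **spatial-lag SAR**
model y = ρWy + Xβ + ε whose weights reuse the GWR kernel, because the
local results of GWR are inherently spatially autocorrelated (nearby
local models share data) and naive OLS overstates significance.
Moran's I distance-band correlograms (`correlogram()`) make that
inherent autocorrelation visible.

A seeded synthetic-grid generator (`scenario()`, `simulate_palm_grid()`)
produces palm-like richness surfaces with *known* latitude-varying water
and energy effects, so every stage can be validated against ground
truth.

## Worked example

```r
library(gwrshift)
cells <- simulate_palm_grid("predictor_shift", seed = 1)  # ~1500 cells, 33S-34N
tab   <- derive_water_deficit(filter_cells(cells))
kern  <- kernel_spec("bisquare", 1200)

sel_w <- select_model(tab, variable_set("water"), kern)
sel_w[order(sel_w$aicc), c("subset", "aicc", "delta_aicc")]
#>      subset    aicc delta_aicc
#>  AP+MPDM+WD 11094.8      0.000
#>       AP+WD 11307.2    212.414
#>     MPDM+WD 11358.3    263.481
#>     AP+MPDM 11491.9    397.099
#>          AP 11798.7    703.914
#>          WD 11853.0    758.259
#>        MPDM 12120.7   1025.890
```

The full water model wins by a ΔAICc margin of 212.  Fitting the
combined model and partitioning:

```r
sel_e <- select_model(tab, variable_set("energy"), kern)
fit_c <- fit_gwr(tab, combined_model(sel_w, sel_e), kern)
fit_c
#> GWR fit: richness ~ AP + MPDM + WD + MAT + MTCM + PET
#>   kernel bisquare_1200, n = 1541, tr(S) = 72.571, AICc = 10739.56
#>   local R^2: min 0.521, median 0.879, max 0.971

part <- partition_local(attr(sel_w, "best_fit"), attr(sel_e, "best_fit"), fit_c)
tg   <- trend_grid(list(bisquare_1200 = part), methods = c("ols", "sar"))
tg[tg$response %in% c("R_pw", "R_pe"),
   c("response", "hemisphere", "method", "slope", "p_value", "rho")]
#>  response hemisphere method    slope   p_value   rho
#>      R_pe      north    ols  0.73509 8.59e-134    NA
#>      R_pe      north    sar -0.00409  8.15e-01 0.995
#>      R_pw      north    ols -0.68258 2.44e-108    NA
#>      R_pw      north    sar -0.04645  3.40e-03 0.997
#>      R_pe      south    ols  0.72023 2.45e-122    NA
#>      R_pe      south    sar  0.02174  1.29e-01 0.997
#>      R_pw      south    ols -0.90063 3.41e-276    NA
#>      R_pw      south    sar -0.05574  6.85e-10 0.997
```

The standardized slopes recover the generator's built-in shift: pure
water *decreases* with absolute latitude (negative slopes) and pure
energy *increases* (positive slopes), in both hemispheres.  The SAR
slopes are strongly attenuated and sometimes non-significant — the
expected consequence of removing the inherent autocorrelation (ρ ≈
0.99) before judging the trend.

`run_pipeline(pipeline_config(scenario = "predictor_shift", seed = 1,
output_dir = "out"))` runs the whole chain over all four kernels and
writes every stage's CSV plus a JSON metadata file; YAML configuration
files are supported via `read_pipeline_config()`.

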