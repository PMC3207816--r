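---
title: "Detecting latitudinal shifts in water vs. energy control of species richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting latitudinal shifts in water vs. energy control of species richness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gwrshift)
```

## The question and the model

Water–energy dynamics theory holds that broad-scale species richness is
jointly limited by liquid water and ambient energy, with water dominant
where energy is plentiful (low latitudes) and energy dominant where it
is scarce (high latitudes).  For a strictly tropical group on a
contiguous 1°×1° richness grid, the testable corollary is that the
*local* explanatory power of water-related climate variables should
decline with absolute latitude while that of energy-related variables
rises — in both hemispheres.

`gwrshift` operationalizes this in five stages.

**1. Local modelling (GWR).**  For each cell $i$, a weighted least
squares regression of richness on climate is fitted with weights
$w_{ij} = K(d_{ij}/b)$ from a fixed spatial kernel:
bi-square $K(u) = (1-u^2)^2$ for $u<1$ (zero beyond, continuous and
near-Gaussian), or the moving window (indicator) kernel.  The focal
cell participates in its own regression with weight 1.  Adaptive
bandwidths are deliberately not offered: with a fixed kernel the
marginal (high-latitude) cells are modelled at the same spatial scale
as the core, which is the point of the comparison.  Bandwidths of
1200 km and 1800 km bracket a scale that is local relative to a
~10,000 km study extent yet still pools hundreds of 1° cells; smaller
bandwidths over-fit (local $R^2 \to 1$), larger ones approach the
global model.

**2. Model selection (AICc).**  Within the water set
$\{AP, MPDM, WD\}$ and energy set $\{MAT, MTCM, PET\}$ (water deficit
$WD = PET - AET$; AET itself is excluded because it confounds water and
energy), all seven subsets of one to three variables are ranked by the
GWR small-sample corrected AIC
$$\mathrm{AICc} = 2n\ln\hat\sigma + n\ln 2\pi +
  n\,\frac{n + \mathrm{tr}(S)}{n - 2 - \mathrm{tr}(S)},$$
where $\mathrm{tr}(S)$ is the trace of the GWR hat matrix (effective
number of parameters) and $\hat\sigma^2 = RSS/n$.  The same formula
with $\mathrm{tr}(S) = p+1$ scores the matched global OLS model, so
$\mathrm{AICc}_{OLS} - \mathrm{AICc}_{GWR}$ is a like-for-like measure
of spatial non-stationarity.  This is the standard GWR AICc; the
convention is recorded in every run's metadata.

**3. Variation partitioning.**  With $R_w$, $R_e$, $R_t$ the local
$R^2$ of the best water, best energy and combined models, the pure
fractions are $R_{pw} = R_t - R_e$ and $R_{pe} = R_t - R_w$, and the
shared fraction is $R_w + R_e - R_t$.  Because the three local models
are nested least-squares fits sharing one weight vector, the pure
fractions are non-negative by construction; the package treats any
negative value beyond $-10^{-9}$ as an internal-consistency error
rather than data, and clamps values inside that floating-point band to
zero (recomputing the shared fraction so the identity
$R_{pw} + R_{pe} + \text{shared} = R_t$ holds exactly).  The shared
fraction is reported even though only the pure fractions enter the
headline test: with collinear water and energy fields it is the piece
that moves.

**4. Inherent autocorrelation and SAR.**  Neighboring local models
share most of their data, so every local surface (coefficients, $R^2$,
fractions) is spatially autocorrelated *by construction*, at the scale
of the kernel.  `correlogram()` (distance-band Moran's I, half-open
bands, default ten equal-width bands; the final band is right-closed so
exhaustive bands account for every ordered pair) documents this.
Because of it, OLS regressions of local fractions on latitude overstate
significance badly, so trends are also fitted with a maximum-likelihood
spatial-lag SAR model $y = \rho W y + X\beta + \varepsilon$ whose
weights reuse the *same* kernel family and bandwidth as the GWR that
produced the response, zero-diagonal and row-standardized.  Row
standardization puts the upper end of the admissible $\rho$ interval at
1 and is the dominant convention for lag models; the symmetric
raw-kernel alternative is available for sensitivity runs.  The profile
log-likelihood uses $\ln|I-\rho W| = \sum_i \ln(1-\rho\lambda_i)$ with
eigenvalues obtained from the similar symmetric form of $W$ (real
spectrum guaranteed), maximized by bounded scalar search (tolerance
$10^{-8}$); a maximizer within $10^{-6}$ of an interval end is flagged
non-converged.  Standard errors for $\beta$ are conditional on
$\hat\rho$ ($\hat\sigma^2 (X'X)^{-1}$) with two-sided z-tests — the
reported quantities (standardized slope, $p<0.05$ flag) are robust to
this choice at the precision used.

**5. Latitudinal trends.**  Each response in
$\{R_w, R_e, R_{pw}, R_{pe}\}$ and absolute latitude are z-scored
(sample sd, $n-1$) within each hemisphere (equator cells go north by
convention; on half-degree-centered grids the boundary never occurs)
and regressed by OLS and SAR, for every kernel — a 4 responses × 2
hemispheres × 4 kernels grid per method, with per-test $p<0.05$ flags
and no multiple-testing correction (the sign pattern across the grid,
not any single test, is the result).  SAR weights are rebuilt on each
hemisphere's cells alone, since the hemispheres are analyzed
separately.

## Numerical choices

* Great-circle distances: haversine on a 6371.0 km sphere between cell
  centers.
* Local solves: thin SVD of the $\sqrt{w}$-scaled design (rank
  revealing, no explicit inversion); singular values below $10^{-10}$
  of the largest are truncated.  A local fit is *unreliable* — its
  coefficients and $R^2$ withheld as `NA` and the cell excluded
  (listwise, with counts logged) from trend responses — when fewer than
  $p+2$ observations carry positive weight or the weighted design's
  condition number exceeds $10^{10}$.
* Local $R^2$ is weighted, around the weighted mean.
* Kernel boundaries: moving window inclusive at $d=b$; the bi-square
  taper is already zero there.
* The per-cell loop is compiled (RcppArmadillo), which keeps a
  ~1500-cell, four-kernel full run in the tens of seconds; all linear
  algebra is checked in the test suite against independently coded
  normal-equation, dense-hat-matrix and dense-log-determinant oracles.

## The synthetic test bed

Real palm-range and climate rasters are external data products, so
validation runs on a seeded generator that reproduces the *statistical*
structure the analysis assumes — and nothing more (no dispersal,
history, or real coastlines).  The default grid spans 33°S–34°N and 23°
of longitude (1541 one-degree cells, matching the ~1500-cell scale of
the palm analyses).  Each climate variable is a deterministic
absolute-latitude trend plus a spatially smoothed Gaussian field
(white noise convolved with a 600-km bi-square kernel — convolution
rather than spectral synthesis, for exact seeding); shared latent
fields induce realistic within-set collinearity, and the cross-set
latent correlation is pinned *exactly* at `rho_we` by orthogonalizing
the realized fields before mixing (default 0.3; 0.8 in the `collinear`
preset).  Richness is
$\mathrm{round}(\max(0, a + \beta_w(\varphi)W + \beta_e(\varphi)E +
\varepsilon))$ with $W, E$ the standardized first principal axes of the
two variable triples (computed by the generator's own power iteration),
$\beta_w(\varphi) = b_{w0} - b_{w1}|\varphi|$ and
$\beta_e(\varphi) = b_{e0} + b_{e1}|\varphi|$.  The defaults
($a = 60$, $b_{w0} = 35$, $b_{e0} = 5$, $b_{w1} = b_{e1} = 0.8$, noise
sd 8) make water dominant at the equator, energy dominant at the
margins, and richness peak near the equator and fall toward zero at the
grid edges — the qualitative shape of a megathermal richness gradient.
A rounded truncated-linear response (not a count distribution) is used
deliberately: the GWR is Gaussian on raw richness, so the generator
matches the analysis model; a Poisson option would test robustness, not
correctness, and is left as future work.  The true coefficient surfaces
are attached to every simulated table for recovery tests.

Presets: `stationary` ($b_{w1}=b_{e1}=0$), `predictor_shift` (the
pattern under test), `shift_with_sac` (adds 800-km-range autocorrelated
richness errors), `collinear`.

## What passing tests do and do not show

The suite demonstrates that the implementation is faithful (oracle
equivalences, degenerate-bandwidth identities, partition identities,
parameter recovery) and that the *pipeline* recovers a built-in
predictor shift: on `predictor_shift` grids the standardized slope of
pure water is negative and of pure energy positive, in both
hemispheres, for both kernels and both trend methods, with SAR slopes
attenuated relative to OLS.  It does **not** show that real palm data
contain such a shift, nor that the synthetic climate fields resemble
real climate beyond their trend, smoothness and collinearity structure.

Two empirical caveats surfaced by the test bed are worth knowing:

* **Inherent autocorrelation inflates naive OLS trend tests.**  Under
  the `stationary` scenario (no true shift, i.i.d. errors) the OLS
  trend test on local fractions rejects far above its nominal level —
  the local surfaces are smooth random fields, so the effective sample
  size is tens, not ~750.  The machinery itself is calibrated: permuting
  a response across cells (destroying the autocorrelation) restores the
  nominal rejection rate, and the SAR test rejects no more often than
  OLS under autocorrelated nulls.  This is the statistical argument for
  reading the SAR columns, not the OLS columns, as the inferential
  result.
* **Edge effects.**  Kernel windows truncated at the grid's north/south
  edges change local predictor variance systematically with latitude,
  which under the stationary scenario induces a small but systematic
  negative drift in the pure-water trend (mean standardized OLS slope
  ≈ −0.2 at the default scale).  Effects of this magnitude near the
  margin of significance should therefore not be over-interpreted on
  real grids either.

For collinearity-sensitive properties (shared fraction near zero under
orthogonal fields; shared fraction rising monotonically with `rho_we`)
the test suite shortens the smoothing range to 200 km and the bandwidth
to 600 km: a window must contain many independent climate patches for
within-window sample correlations to approximate the imposed global
correlation.  At the palm-like defaults the windows are only about two
smoothing ranges wide and window-level sampling correlation dominates —
itself a useful reminder of how local models behave when the predictor
fields are smooth.

## Problem sizes used in validation

Oracle and identity checks run on 15–600-cell instances; SAR recovery
on 20×20 lattices with 100 replicates; sign-pattern recovery on 20
seeds of the full 1541-cell grid (both 1200-km kernels, both methods);
null-calibration runs on 50 seeds.  These sizes were chosen so the
whole suite exercises the study-scale grid while remaining a
few-minutes run on a single CPU.

## Known limitations

* Fixed kernels only; no bandwidth cross-validation or adaptive
  kernels (a deliberate scope choice, matching the marginal-area
  rationale above).
* No Monte-Carlo tests of coefficient non-stationarity, no
  semi-parametric (mixed) GWR, no SAR-error or Durbin variants.
* Dense $n\times n$ weight matrices: fine to a few thousand cells, not
  for $n \gg 10^4$.
* The SAR $\beta$ standard errors are conditional on $\hat\rho$; a full
  information matrix would widen them slightly.
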