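---
title: "Models and methods for spatially autocorrelated lattice data"
author: "spatglm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for spatially autocorrelated lattice data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatglm)
```

## The problem

Grid-based ecological data — species counts, presence/absence records,
trait or pollution indices sampled on a raster — usually violate the
independence assumption of ordinary regression: cells close to one another
hold more similar values than distant cells.  Ignoring this spatial
autocorrelation does not much bias the coefficients of a correctly
specified model, but it biases their standard errors and, when an
unmeasured *smooth* environmental field is correlated with a covariate, it
biases the coefficients too.  **spatglm** provides two complementary
remedies for GLM-type models (Gaussian, binomial 0/1, Poisson; canonical
links), together with the diagnostics and model-selection machinery
around them:

* **GEE** — generalised estimating equations replace the diagonal GLM
  variance with a working variance–covariance matrix
  \(V = \phi A^{1/2} R A^{1/2}\), solving
  \(\sum D^\top V^{-1}(y-\mu) = 0\) by Fisher scoring.
* **WRM** — wavelet-revised models remove the smooth (low-frequency)
  components of the response *and* all covariates inside every step of
  the IRLS iteration, so the regression is carried by the fine-scale
  (detail) variation, which is the part unaffected by smooth confounding.

## Working correlation structures (GEE)

`gee(..., corstr = )` supports:

* `independence` — \(R = I\); identical to the GLM (this equality is
  asserted to `1e-8` in the test suite).
* `fixed` — an isotropic power function \(R_{ij} = a^{d_{ij}}\) with
  \(d_{ij}\) the Euclidean distance between cells.  The base \(a\) is
  estimated once by least squares of \(\hat\rho(d) = a^d\) on the Moran's
  I correlogram of the comparison GLM's Pearson residuals (bins with no
  pairs are dropped; the bin holding nearest-neighbour pairs is taken as
  \(d = 1\)), then frozen; it never changes during the scoring
  iterations.  For a Gaussian model this reproduces closed-form GLS.
* `exchangeable`, `quadratic` — block-diagonal \(R\) over non-overlapping
  `cluster` × `cluster` tiles of the grid (default 3).  Within-block
  correlation parameters are moment-estimated from products of Pearson
  residuals, alternating with coefficient updates: exchangeable
  constrains all within-block parameters equal, quadratic constrains them
  equal at equal within-block distance (one parameter per distinct
  pairwise distance inside a tile; partially observed tiles simply form
  smaller blocks).  These are the memory-safe options: `fixed` needs an
  \(n \times n\) matrix and is refused above \(n = 20{,}000\).

Dispersion \(\phi\) is the Pearson moment estimate unless
`scale_fix = TRUE`.  Standard errors are robust (sandwich over blocks) for
independence and the clustered structures; for `fixed` the whole lattice
is a single correlation block, a one-cluster sandwich is degenerate, and
the model-based covariance is reported instead.  Model comparison uses
Pan's quasi-likelihood information criterion
\(QIC = -2Q(\hat\beta; I) + 2\,\mathrm{tr}(\hat\Omega_I^{-1}\hat V_r)\),
with \(\hat\Omega_I^{-1} = X^\top A X/\phi\) the independence information
at the fitted means and \(\hat V_r\) the robust covariance.  *Normalised*
Pearson residuals \(L^{-1} r\) (with \(R = LL^\top\)) are used to check how
far the autocorrelation was reduced.

## Wavelet machinery

All wavelet operations are built on separable 2-D filter banks for the
haar and d4 (Daubechies extremal-phase, 4-tap) families, in both the
decimated (`dwt`) and maximal-overlap (`modwt`) forms, with periodic
boundary treatment.  Observations are first embedded in the smallest
\(2^J \times 2^J\) square holding `padzone` times the coordinate bounding
box; unobserved cells take zeros, the mean (default), or mirror-reflected
boundary values — boundary effects are controlled entirely by this
padding zone, which is why the filters themselves can stay periodic.
Unobserved cells *inside* the bounding box are filled with the pad value,
never interpolated (a log-free, simple rule; mirror reflection cannot
reach interior holes).

Components are returned as reconstructed full-resolution fields
(multiresolution analysis), so "the detail at scale s" is defined at
every observation cell even for the decimated transform.  Two exact
identities are enforced by construction and verified in the tests:
telescoping, smooth(s) = smooth(s+1) + detail(s+1), and perfect
reconstruction.  `upscale()` renders smooth components at increasing
scale (dyadic coarsening); `wavelet_varcov()` computes wavelet variance
and covariance per level from the modwt coefficients (d4/modwt default,
the numerically best-behaved combination for this purpose), normalised by
the number of grid cells so the per-level variances plus the final smooth
energy add up exactly to the field's variance.

## The wavelet-revised model

At IRLS iteration *t* the working response
\(z = \eta + (y-\mu)g'(\mu)\) and weights \(W = 1/(V(\mu)g'(\mu)^2)\) are
formed as usual; then the high-pass filter at `level` L (discarding
smooth(L)) is applied to \(z\) and to every non-constant design column,
and the weighted least squares on the filtered quantities yields the next
slope vector.  Two design choices deserve explanation:

* **The intercept.**  A constant column is pure smooth and would be
  annihilated by the filter, so it is kept unfiltered.  But the filtered
  working response is mean-free, so the WLS intercept cannot anchor the
  mean level of the fit — for log and logit links the iteration then
  computes weights at a linear predictor far below the data and
  oscillates.  The intercept is therefore re-anchored at each iteration
  to its profile maximum likelihood given the slope offset (closed form
  for Gaussian/Poisson, a one-dimensional Newton step for binomial).
  Slopes are untouched by this: for a Gaussian model they equal the OLS
  solution on the filtered data exactly.
* **Residuals.**  The weighted residuals of the filtered regression,
  \(\sqrt W (z_f - X_f\hat\beta_{wls})\), are reported as the model's
  Pearson residuals.  For *autocorrelation diagnosis*, however,
  cell-space high-pass residuals are misleading: they are a projection
  onto the detail subspace (orthogonal to constants), which forces
  lag-one Moran's I of about \(-0.13\) to \(-0.20\) even when the model is
  perfect.  The diagnostic profile (`ac_model`, and
  `residuals$whitened`) therefore uses the *decimated orthonormal DWT
  detail coefficients* of the response-scale Pearson residuals, placed at
  representative cells of their dyadic blocks: under a correct model
  these coefficients are exactly uncorrelated, so their Moran's I is
  centred at \(-1/(m-1)\), while spatial structure the filter failed to
  remove still shows up as positive correlation among them.

Fitted values, predictions and AIC/AICc are computed on the original
scale from \(\hat\beta\) (`aic_calc()` evaluates the exact log
likelihood at the fitted means; the Gaussian error variance is profiled
out and counted as one parameter).  Dispersion is fixed at 1 for
binomial/Poisson unless requested otherwise.  Convergence is declared at
a relative coefficient change below `1e-6` (at most 200 iterations); for
log/logit links the linear predictor is clamped at ±30 and a diverging
weighted-least-squares step stops the iteration with a warning rather
than propagating non-finite values.

`scale_wmrr()` replaces the high-pass filter with a single-scale
component extractor (detail or smooth at scale *s*) for scale-specific
inference; at scale 1 with details it coincides with `wrm(level = 1)`
(the two share a code path, since detail(1) = data − smooth(1)).
Significance tests should not be compared across scales — the effective
sample size changes with scale — which is what the AIC-based multimodel
machinery below is for.

## Moran's I correlograms

`acfft()` computes a binned Moran's I profile: bin *k* covers
\([lim_1 + (k-1)h,\; lim_2 + (k-1)h)\) with \(h = lim_2 - lim_1\)
(defaults 0, 1, `dmax = 10`), distances are Euclidean between integer
cell centres, bins are half-open, and the variable is centred internally.
All ordered-pair sums are evaluated by 2-D FFT cross-correlation on a
zero-padded embedding (at least twice the grid side, so the correlation
is linear, not circular); `moran_bruteforce()` is the O(n²) oracle and
the two agree to \(10^{-10}\) on every tested instance.  Note that with
the default limits the first bin \([0,1)\) contains no lattice pairs and
is reported as `NaN`; `moran_lag1()` measures the nearest-neighbour bin
\([0, 1.01)\) directly.

## Model selection and relative importance

`step_spatial()` performs backward selection (QIC for GEE, AIC or AICc
for wavelet models), always respecting the hierarchy of terms: a main
effect is never removed while an interaction or polynomial containing it
remains (the rule is syntactic — a term blocks removal of any main effect
whose symbol occurs in it).  Removal requires a strict criterion
improvement; ties among deletions are broken by term order.  Forward
selection is deliberately not offered.  `mmi_gee()` / `mmi_wmrr()`
enumerate all \(2^p\) term subsets (refused above \(p = 12\)), attach
criterion deltas and Akaike weights \(w \propto e^{-\Delta/2}\) (failed
subset fits are flagged and excluded from the normalisation), and sort by
criterion with ties favouring smaller models.  `rvi()` runs the
all-subsets table at each scale `1..maxlevel` of the multiresolution
regression and sums, per variable, the weights of the models containing
it — a picture of which spatial resolution carries each predictor's
support.

## Spatially corrected accuracy measures

For presence/absence predictions the classical confusion-matrix measures
treat a false presence next to an observed presence exactly like one far
away.  The spatial variants (`spatial = TRUE` in `th_dep()` /
`th_indep()`) judge each cell against the **neighbourhood envelope** of
its actual value: the interval between the 0/1 actual \(a_i\) and its
mean \(a^*_i\) over the 3×3 queen neighbourhood (`smooth_actuals()`),
taking the point of the envelope closest to the prediction.  Because
\(a_i\) is always an endpoint, predictions identical to the actuals score
perfectly; because the envelope of an absence adjacent to presences
reaches up to \(a^*_i\), near misses earn partial credit; and the
spatial sensitivity/specificity are never below their classical values.
`th_dep()` maps effective actuals and predictions into four ordinal
classes by the cut points \(\{t/2, t, (1+t)/2\}\) and scores the 4×4
table with a weighted Cohen's kappa (linear weights
\(w_{ij} = 1 - |i-j|/3\)); collapsing classes {3,4} to "positive" gives
sensitivity and specificity.  `th_indep()` sweeps thresholds over
midpoints of the sorted unique predictions and accumulates a soft
confusion matrix from the envelope; AUC is the trapezoid over the
resulting ROC and TSS the maximum of sensitivity + specificity − 1.
With `spatial = FALSE` both functions reduce *exactly* to the textbook
kappa and the Mann–Whitney AUC (asserted to \(10^{-10}\) against
independently coded oracles).  One known property of the envelope
construction: the chance-level value of the spatial kappa is slightly
above zero, because chance agreement with a neighbour also earns partial
credit; the classical kappa keeps its exact chance-zero calibration.

An earlier candidate instantiation — replacing the actuals by \(a^*\)
additively in the soft counts — was rejected: fractional soft labels put
a hard ceiling on the attainable AUC (about 0.95 for perfect predictions
on smooth fields, far lower on sharp ones), so displaced predictions
scored *worse* spatially than classically, inverting the construction's
purpose.

## Synthetic data

The generators exist so every claim above is testable without external
data; they emulate the statistical shape of gridded count and
presence/absence data sets, not any particular real data set.

`sim_count_grid()` builds, on an `n_side` × `n_side` lattice (default
24), two covariates as Gaussian-kernel-smoothed white noise (kernel sd
`ac_range`, default 1 cell — autocorrelated but still rich in fine-scale
detail) and a Poisson (or Gaussian/binomial) response from
\(\eta = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + u\) with true
\(\beta = (0.5, 0.3, -0.4)\).  The spatial random field \(u\)
(sd `field_sd`, default 0.8 — a strong smooth field) is built by further
blurring (range `2 * ac_range`) so it is always smoother than the
covariates, and `confounder_strength` \(\rho\) rotates it towards the
smooth part of \(x_1\): \(\rho = 0\) gives a pure spatial random effect
(GLM slopes recover the truth, which the tests verify), \(\rho = 1\)
maximal confounding (naive slopes biased by ≈ 0.5–0.6).  Because the
confounder shares only the *smooth* part of \(x_1\), the fine-scale
detail remains informative — exactly the structure WRM filtering and GEE
whitening can exploit.  The package's acceptance checks run the
residual-autocorrelation comparison at \(\rho = 0.5\) (a partial
confounder, the representative case) and the slope-bias comparison at
\(\rho = 1\) (the worst case).

`sim_presence_preds()` thresholds a smooth field at the
\(1-\text{prevalence}\) quantile (default 0.3) for clustered presences
and maps the same field — optionally displaced by `shift_cells` — through
a steep logistic into a probability surface; the displacement creates
controllable near-miss structure.  Defaults (`ac_range = 1`,
`steepness = 10`) give compact patches a one-cell shift genuinely
disrupts, which is the regime where spatial and classical accuracy
measures disagree.  All generators are deterministic given `seed`,
restore the caller's RNG state, and return a ground-truth sidecar.

What the generators do *not* emulate: anisotropy, non-stationary
autocorrelation, irregular survey gaps, overdispersion beyond the
lognormal-type field, and detection error.  Passing tests on these
fixtures therefore demonstrate correctness of the algorithms under
isotropic stationary smoothing, not robustness to all field data.

## Numerical choices and limitations

* Problem sizes in the tests: 16–24-cell grid sides, 100-seed Monte-Carlo
  loops; chosen so the whole suite runs in well under a minute of compute
  per file while keeping Monte-Carlo error far below the asserted
  margins.
* GEE Fisher scoring: relative tolerance `1e-8`, ≤ 50 iterations; the
  clustered outer loop alternates to a joint tolerance of `1e-6` (≤ 25
  rounds).  Working correlations that fail positive definiteness are
  shrunk towards the identity with a warning; a fitted power base outside
  \([0, 0.99]\) is clamped with a warning.
* WRM: tolerance `1e-6`, ≤ 200 iterations, ±30 clamp on the linear
  predictor for log/logit links; non-convergence and divergence are
  flagged, never silent.
* Moran bins with no pairs give `NaN`; a constant input gives an all-`NaN`
  profile with a warning.
* The `fixed` GEE stores a dense \(n \times n\) correlation; use the
  clustered structures for large lattices.
* p-values in the summaries use a normal reference; with small lattices
  they are approximate, and across scales of `scale_wmrr()` they should
  not be compared at all.
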