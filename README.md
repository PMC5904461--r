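# spatglm

Regression and model evaluation for **spatially autocorrelated lattice
data**: grid-based observations (species counts, presence/absence,
environmental indices) where nearby cells are more similar than distant
ones, so the i.i.d.-error assumption of ordinary GLMs fails.

The package provides, for Gaussian, binomial (0/1) and Poisson responses
with canonical links:

* **Spatial GEE** — generalised estimating equations with working
  variance `V = φ A^{1/2} R A^{1/2}`; `R` can be the identity
  (= ordinary GLM), a frozen isotropic power function `R_ij = a^(d_ij)`
  adapted to the residual correlogram of the comparison GLM, or a
  block-diagonal matrix over grid tiles with moment-estimated
  exchangeable or distance-dependent (quadratic) parameters.  Model
  comparison by QIC; whitening check via normalised Pearson residuals.
* **Wavelet-revised models (WRM)** — GLMs in which the smooth
  (low-frequency) wavelet components of the response *and* all covariates
  are removed inside every IRLS step, so the fit is carried by fine-scale
  detail that smooth spatial confounders cannot reach.  Haar and
  Daubechies-4 families, decimated and maximal-overlap transforms,
  configurable dyadic padding.
* **Scale-specific multiresolution regression** (`scale_wmrr`), wavelet
  variance/covariance by level (`wavelet_varcov`) and dyadic upscaling
  maps (`upscale`).
* **Moran's I correlograms via FFT** (`acfft`) with an exact
  pair-enumeration oracle (`moran_bruteforce`).
* **Model selection**: hierarchy-respecting backward stepwise selection
  (`step_spatial`), all-subsets multimodel inference with Akaike weights
  (`mmi_gee`, `mmi_wmrr`), relative variable importance across spatial
  scales (`rvi`).
* **Spatially corrected accuracy measures**: weighted 4×4 kappa and
  soft-confusion ROC/AUC/TSS that give partial credit to predictions
  wrong in place but right in neighbourhood (`th_dep`, `th_indep`), with
  exact classical counterparts.
* **Seeded generators** for spatially autocorrelated synthetic lattices
  with known ground truth (`sim_count_grid`, `sim_dyadic_grid`,
  `sim_presence_preds`).

## Worked example

```r
library(spatglm)

# a 20x20 Poisson lattice with autocorrelated covariates and a smooth
# confounding field (true slopes: pollution 0.3, exposure -0.4)
sim <- sim_count_grid(n_side = 20, confounder_strength = 0.5, seed = 11)

mgee <- gee(count ~ pollution + exposure, family = "poisson",
            data = sim$data, coord = sim$coords, corstr = "fixed")
summary(mgee, printAutoCorPars = TRUE)
#> Spatial GEE, family poisson , corstr = fixed
#>              Estimate Std. Error z value  Pr(>|z|)
#> (Intercept)  0.647881   0.167958  3.8574 0.0001146 ***
#> pollution    0.349749   0.072858  4.8005 1.583e-06 ***
#> exposure    -0.379777   0.074232 -5.1161 3.119e-07 ***
#> QIC: 92.819   dispersion: 1.9257
#> Working correlation parameters:
#> $a
#> [1] 0.517
#> Residual Moran's I (GLM):   0.44 0.331 0.198 0.091 0.009
#> Residual Moran's I (GEE):   -0.081 0.057 0.012 0.005 0.031
```

The GLM's Pearson residuals are strongly autocorrelated (Moran's I 0.44
at distance 1); the fitted power base `a = 0.517` whitens them (−0.08),
and the `exposure` slope moves back towards its true value −0.4.

```r
mwrm <- wrm(count ~ pollution + exposure, family = "poisson",
            data = sim$data, coord = sim$coords, level = 1)
summary(mwrm)
#> Wavelet-revised model, family poisson
#>              Estimate Std. Error z value  Pr(>|z|)
#> (Intercept)  0.763896   0.033573 22.7535 < 2.2e-16 ***
#> pollution    0.353323   0.071244  4.9593 7.074e-07 ***
#> exposure    -0.287909   0.069849 -4.1219 3.758e-05 ***
#> AIC: 1575.245   AICc: 1575.305
#> wavelet: haar / dwt  level: 1  padform: mean  padzone: 1
#> Residual Moran's I (WRM): 0.09 0.037 0.009 -0.009

# spatially corrected vs classical accuracy on near-miss predictions
h <- sim_presence_preds(n_side = 20, shift_cells = 1, seed = 2)
th_indep(h$data$actuals, h$data$predictions, h$coords, spatial = TRUE)$AUC
#> [1] 0.918432
th_indep(h$data$actuals, h$data$predictions, h$coords, spatial = FALSE)$AUC
#> [1] 0.8369048
```

The prediction surface is displaced by one cell, so every presence is
"missed" by exactly one cell: the classical AUC drops to 0.84 while the
spatial AUC, crediting the queen neighbourhood, stays at 0.92.

A thin command-line wrapper over the same functions is installed at
`inst/cli/spatglm` (subcommands `simulate`, `glm`, `gee`, `wrm`, `wmrr`,
`acf`, `accuracy`, `upscale`, `covar`, `step`, `mmi`, `rvi`).

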