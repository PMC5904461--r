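Package: spatglm
Title: GLM-Family Regression and Model Evaluation for Spatially Autocorrelated Lattice Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regression analysis of grid-based (lattice) data whose
    residuals are spatially autocorrelated. Provides generalised estimating
    equations (GEE) with independence, fixed isotropic-power and clustered
    (exchangeable, quadratic) working correlation structures; wavelet-revised
    models (WRM) that remove smooth, low-frequency spatial components of the
    response and predictors inside every step of the GLM iteration; scale-
    specific wavelet multiresolution regression; Moran's I correlograms
    computed via fast Fourier transforms; backward stepwise selection and
    multimodel inference across predictors and spatial scales; and spatially
    corrected prediction-accuracy measures (weighted 4x4 kappa, spatial
    AUC and TSS) alongside their classical counterparts. Seeded generators
    for spatially autocorrelated synthetic lattice data sets are included.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
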