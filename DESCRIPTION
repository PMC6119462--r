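Package: GeoForest
Title: Random Forest Spatial Prediction with Buffer-Distance Covariates
    and Kriging Baselines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatial and spatiotemporal interpolation of point-sampled
    environmental variables with random forests trained on geographical
    proximity covariates (Euclidean buffer distances to the observation
    points or to observation classes), with prediction intervals and
    error standard deviations derived from quantile regression forest
    weights. Includes the classical model-based baselines (ordinary
    kriging with method-of-moments variogram estimation and weighted
    least-squares model fitting, Box-Cox and log-normal transforms,
    regression kriging), a cross-validation battery (RMSE, ME, R2,
    Lin's concordance, z-score calibration, accuracy plots, residual
    variogram diagnostics), error-guided second-stage sampling, and a
    download-free synthetic data generator based on Gaussian random
    fields so every workflow is reproducible from code alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
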