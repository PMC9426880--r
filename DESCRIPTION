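Package: dsurf
Title: Density Surface Modelling of Aerial Line-Transect Surveys
Version: 0.1.0
Authors@R:
    person("dsurf", "developers", email = "dsurf@example.org", role = c("aut", "cre"))
Description: Two-stage density surface modelling for aerial line-transect
    distance-sampling surveys of wildlife populations. Stage one fits
    multiple-covariate distance sampling (MCDS) detection functions
    (half-normal or hazard-rate key) by maximum likelihood, ranks candidate
    models by AIC with a parsimony rule, and converts detections into
    Horvitz-Thompson corrected segment abundances. Stage two compresses
    landscape covariates by principal components analysis, fits a Tweedie
    generalized additive model of segment abundance on a bivariate spatial
    smooth and component scores with an effort offset (REML smoothing,
    shrinkage thin-plate splines, all-subsets AIC selection), propagates
    detection-function uncertainty into the spatial model, and predicts
    density, abundance and coefficient-of-variation surfaces over a grid.
    A synthetic-survey generator with known truth supports verification of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1),
    mgcv
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
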