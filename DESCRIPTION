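Package: somkin
Title: Multi-Pool First-Order Soil Organic Matter Decomposition Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits constrained one-, two- and three-pool first-order decomposition
    models to laboratory soil incubation CO2 time series, summarizes compiled
    kinetics datasets, predicts reference decomposition rates and pool sizes from
    edaphic-climatic covariates with multiple linear regression, random forest and
    gradient boosting (with recursive feature elimination and AIC-based model
    selection), and applies trained models over gridded covariates to produce
    parameter maps with input- and model-structure relative uncertainty and
    latitudinal profiles. Includes a seeded synthetic-data generator (incubation
    curves, compiled-style tables with a Gaussian-copula covariate structure, and
    covariate rasters) so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    randomForest,
    xgboost,
    Matrix,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
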