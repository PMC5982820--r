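Package: faGBLUP
Title: Factor-Analytic Multi-Environment Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-stage genomic prediction for multi-environment plant
    breeding trials. Fits linear mixed models with an additive genetic
    component (genomic-kernel covariance among lines) and a residual genetic
    component (identity kernel), each with a diagonal or factor-analytic
    covariance structure across environments, by restricted maximum
    likelihood. Provides marker quality control and genomic relationship
    matrices, BLUP extraction of breeding values and total genotypic values,
    generalized heritability from average pairwise prediction error
    variances, environment clustering on genetic correlations, AIC and
    likelihood-ratio model ladders, replicated cross-validation of
    prediction accuracy with relative-accuracy statistics, and a simulator
    for two-phase (field and laboratory) partially replicated trial designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'fa.R'
    'markers.R'
    'simulate.R'
    'reml-common.R'
    'reml-dense.R'
    'reml-eigen.R'
    'reml-fit.R'
    'oracle.R'
    'prediction.R'
    'model-selection.R'
    'crossval.R'
    'io.R'
    'pipeline.R'
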