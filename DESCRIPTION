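Package: slehorizon
Title: Temporal Machine Learning for Predicting Lupus Hospitalization
    from Longitudinal Clinical Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for predicting systemic lupus erythematosus (SLE)
    hospitalization from longitudinal, irregularly sampled clinical
    records. Implements two temporal modelling strategies over a shared
    windowing framework: a Differential approach that augments a flat
    feature panel with lagged between-step change variables and fits a
    majority-voting ensemble of six non-temporal learners over balanced
    bootstrap bags, and an LSTM sequence classifier trained on
    oversampled equal-length sequences. Includes a synthetic cohort
    generator with a latent disease-activity process so that every
    pipeline stage (6-month binning, linear interpolation/extrapolation
    imputation, sliding-window extraction for observation-window by
    prediction-horizon tasks, class rebalancing, nested cross-validation
    and metric grids) can be exercised and validated without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest,
    e1071,
    nnet,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
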