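Package: resilpig
Title: Resilience Phenotyping from Longitudinal Pig Weight and Feed Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies general resilience of growing pigs from longitudinal
    automated-feeding-station records. Provides a multi-stage quality-control
    cascade for daily weight, feed-intake and feeding-behaviour data,
    derivation of deviation-based resilience traits (log residual variance
    after Gompertz growth-curve fitting, linear-model lnMSE, standardized
    weight variance, skewness, lag-one autocorrelation, trajectory
    straightness and mean speed, quantile-regression off-feed days), REML
    animal-model estimation of variance components with pedigree, genomic and
    single-step (H matrix) relationships, masking-based cross-validation of
    breeding values, robustness analysis over observation frequency and
    period, and a synthetic-data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    quantreg,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    lme4,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
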