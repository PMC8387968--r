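Package: florastat
Title: Resampling-Based Evaluation of Automated Plant-Identification Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical pipeline for evaluating the accuracy of automated
    plant-identification tools against expert-verified observations.
    Observations are scored into four ordered identification classes
    (species, genus, family, none), pseudoreplication is controlled by
    iterated one-observation-per-species subsampling, and accuracy is
    compared across study settings and species groups with fixed-marginal
    (Patefield) randomization tests, Monte-Carlo Fisher exact tests and
    cell z-scores. Image characteristics are modelled with a binomial
    random-intercept model with type-III Wald tests, estimated marginal
    means and compact-letter post hoc grouping, and training-image effort
    is related to identification success with correlation and group
    comparisons. A synthetic-data generator with exported ground truth
    supports calibration and parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    car
Config/testthat/edition: 3
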