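Package: hbtraj
Title: Longitudinal Maternal Hemoglobin Trajectories and Birth Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Five complementary statistical strategies for relating repeated
    maternal hemoglobin (Hb) measurements during pregnancy to binary birth
    outcomes (low birth weight, preterm birth, small-for-gestational-age):
    sequential-residual logistic regression, a two-stage mixed-effects model
    using subject-level BLUPs as predictors, a distributed lag non-linear
    logistic model with an exposure-by-lag cross-basis, an outcome-stratified
    additive mixed model of the Hb trajectory, and group-based trajectory
    modeling by a finite mixture of polynomial curves fitted with a
    multi-start EM algorithm. A synthetic cohort generator with known ground
    truth (random effects, latent classes, exposure-window effects) makes
    every method testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
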