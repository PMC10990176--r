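Package: kinpanel
Title: Longitudinal Panel Models for Kinesiophobia and Accelerometer-Measured
    Physical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying the longitudinal interplay between fear of
    movement (kinesiophobia, measured with the 13-item TSK-NL Heart
    questionnaire) and accelerometer-measured physical activity in the first
    twelve weeks after cardiac hospitalization. Provides a seeded synthetic
    cohort generator with a latent trait/state dependence structure, MET-based
    activity-intensity aggregation, Little's MCAR test, chained-equations
    multiple imputation with Rubin pooling, a path-model (RAM) engine with
    maximum-likelihood estimation and chi-square/CFI/TLI fit assessment, and
    builders for the random-intercept cross-lagged panel model and its
    trait-kinesiophobia alternative.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
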