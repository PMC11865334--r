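Package: spirodiscord
Title: Discordance Between Race-Specific and Race-Neutral Spirometry
    Reference Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate spirometry reference equations (LMS and
    polynomial engines) to z-scores and limits of normal, classify
    obstructive and restrictive spirometric patterns, quantify discordance
    between two equation systems with Cohen's kappa and a full
    confusion-matrix metric suite, develop best-fit reference equations
    with a BIC-based test of whether race is a necessary covariate, and
    validate models by repeated k-fold cross-validation with permutation
    and bootstrap RMSE tests. A synthetic cohort generator emulating the
    demographic strata of a large clinical pulmonary-function dataset
    makes the whole pipeline exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
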