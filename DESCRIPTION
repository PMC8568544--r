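Package: oadcompare
Title: Multi-Arm Real-World Comparison of Oral Antidiabetic Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-arm observational comparisons of
    oral antidiabetic therapies on glycemic control, hypoglycemia,
    health-related quality of life and cost outcomes. Provides therapy-arm
    classification under intent-to-treat and on-treatment rules, clinically
    anchored covariate construction, unadjusted subgroup comparisons with
    compact letter display, covariate-adjusted predictive margins with
    delta-method uncertainty, inverse probability weighting via multinomial
    propensity scores with weighted balance diagnostics, and double-selection
    adaptive-lasso estimation of treatment effects. A synthetic cohort
    generator with confounded multinomial treatment assignment and known true
    arm effects supplies ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    nnet,
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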