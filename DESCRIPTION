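Package: nrbias
Title: Non-Response Bias Analysis for Gender-Blocked Factorial Survey Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying unit non-response bias in blocked factorial
    mailed-survey experiments against a fully observed sampling frame.
    Implements AAPOR RR1 response rates with omnibus homogeneity tests,
    per-correlate bias in percentage points by study-arm manipulation, a
    factorial ANOVA variance partition (eta squared with interaction-df
    pooling), Cohen's h, and prevalence estimation of binary self-reported
    exposures under three missingness mechanisms: complete-case (MCAR),
    multiple imputation with Rubin pooling (MAR), and an
    expectation-maximization fit of a logistic selection model for
    nonignorable missingness (MNAR). A synthetic-cohort generator reproduces
    the design of a 3x2x2 gender-blocked trial of 480 men and 480 women with
    configurable covariate prevalences, outcome models and response
    propensities, so the estimators can be scored against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
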