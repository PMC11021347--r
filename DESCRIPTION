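Package: gigclamp
Title: Glucose-Insulin-Glucagon Feedback Models for Hyperinsulinemic-Euglycemic Clamp Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of the glucose-insulin (GI)
    and glucose-insulin-glucagon (GIG) feedback loops fitted to
    hyperinsulinemic-euglycemic clamp time series, with a synthetic virtual
    cohort generator emulating the clamp under a feedback glucose-infusion
    controller and a 75-g oral glucose tolerance test. Provides per-subject
    parameter estimation by self-adaptive meta-evolutionary programming
    followed by bound-constrained nonlinear least squares, AIC-based selection
    over a configurable family of reduced model variants, composite endocrine
    indices (disposition index over clearance DI/cle, production index over
    clearance PI/cle in numeric and analytic forms, insulin sensitivity index,
    tissue glucose uptake rate, OGTT indices, insulin half-life), and the
    cohort-level statistics used to relate them to glycemia (Spearman
    correlation, standardized major axis regression with a common-slope test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
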