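Package: frcompare
Title: Comparative Functional Response Analysis for Predation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative functional response analysis of feeding
    trials without prey replacement. Fits Rogers' random predator equation by
    maximum likelihood through a robust Lambert-W closed form, determines
    functional response type (Type II vs Type III) by polynomial logistic
    regression, computes nonparametric bootstrap confidence envelopes around
    fitted curves, and derives impact metrics (maximum feeding rate 1/h and
    the functional response ratio a/h). Also provides the factorial
    consumption-rate analysis used alongside functional responses: a
    quasibinomial generalised linear model with Type III analysis of
    deviance, marginality-respecting backward elimination and Wald slope
    contrasts. A stochastic individual-based foraging simulator generates
    synthetic factorial experiments for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
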