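Package: oopburden
Title: Economic Burden of Illness from Out-of-Pocket Health Expenditure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the household economic burden of illness from
    household-survey data: disease-specific mean out-of-pocket (OOP) health
    expenditure via a Bayesian two-stage hurdle model (logistic participation
    hurdle, log-linear consumption hurdle), catastrophic health payment and
    impoverishment incidence via Bayesian logistic regression with
    meta-analytically pooled informative priors, inequality assessment via
    concentration curves and indices over the wealth ranking, and
    inflation-adjusted average annual rates of change. Includes a synthetic
    household-survey generator with analytically known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
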