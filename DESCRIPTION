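Package: pdcua
Title: Cost-Utility and Budget-Impact Modelling of Peritoneal Dialysis
    Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lifetime Markov cohort modelling for economic evaluation of
    dialysis strategies in end-stage renal disease with fluid and sodium
    overload.  Implements a six-state annual-cycle cohort engine
    (continuous ambulatory peritoneal dialysis with glucose or icodextrin
    solutions, automated peritoneal dialysis, haemodialysis, kidney
    transplantation, death), discounted cost/life-year/QALY accumulation,
    incremental cost-effectiveness with dominance classification,
    charge-to-cost and consumer-price-index costing transformations,
    human-capital valuation of informal care, one-way (tornado) and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, mortality-extrapolation and external-input
    scenario analyses, and undiscounted budget-impact projection.
    Parameter sets are plain tabular data (CSV + JSON) with validation,
    synthetic-fixture and random generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
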