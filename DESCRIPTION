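Package: nutricart
Title: Front-of-Pack Label Assignment and Diet-Quality Analysis for Grocery Baskets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating front-of-pack nutrition labels on online
    grocery shopping baskets. Assigns Nutri-Score grades (original food
    algorithm plus a transparent sugar-first surrogate for beverages) and
    UK Multiple Traffic Light colors from per-100 g nutrient panels; scores
    baskets with a nine-component modified Alternative Healthy Eating Index
    (AHEI-2010, maximum 90), serving-weighted average Nutri-Score, nutrient
    totals and per-serving means, spend and calories per dollar; estimates
    label effects with a within-person first-difference crossover model
    (OLS with cluster-robust errors, moderator interactions, food/beverage
    strata); and generates synthetic catalogs, cohorts and
    condition-dependent baskets with known injected label effects so the
    whole pipeline is testable end to end.
License: MIT
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
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
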