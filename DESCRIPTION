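Package: foodagg
Title: Aggregating Branded Food Composition Data into Generic Food Items
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving generic food items from branded packaged-food
    composition databases. Implements a three-step framework: a plausibility
    screen of label-declared nutrients (energy reconciliation against
    Atwater-type factors, saturated-fat and sugar ratio checks), deterministic
    descriptor extraction from product long names within a LanguaL-style
    category hierarchy, and iterative splitting of candidate generic foods on
    ingredient-list and claim descriptors until the coefficient of variation of
    every macronutrient falls below a homogeneity threshold or the remaining
    heterogeneity is inherent. Includes per-group descriptive statistics,
    report tables (generic-name yield, aggregation capacity, CV-grade
    distributions), and a synthetic database generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
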