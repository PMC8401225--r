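Package: foodnpm
Title: Nutrient Profiling Models for Packaged-Food Supply Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the nutrient profiling models (NPMs) used in restrictive
    food-policy analysis of the South African packaged-food supply: the Chile
    Warning Octagon 2019 threshold model, the FSANZ-derived South African
    health-and-nutrition-claims scored model (final and baseline variants), and
    a proposed across-the-board restrictive NPM with free-sugar, added-sodium,
    added-saturated-fat and non-sugar-sweetener qualifying criteria. Includes
    free-sugar estimation rules, non-sugar-sweetener detection from ingredient
    lists, fruit/vegetable/nut/legume content scoring, WHO-aligned per-energy
    sugar limits, whole-food cut-point context checks, category-level supply
    summaries, and a parameterised synthetic supply generator for testing
    classification pipelines without proprietary survey data.
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
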