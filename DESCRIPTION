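Package: savstocks
Title: Aboveground Carbon and Nitrogen Stock Accounting for
    LULC-Stratified Tree Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Plot-based accounting of aboveground carbon and nitrogen
    stocks across land use/land cover (LULC) classes in savannah
    landscapes. Combines species-specific stem-wood carbon and nitrogen
    fractions with configurable allometric biomass models to estimate
    tree-, plot-, class- and landscape-level stocks with standard
    errors, computes stand structure summaries (stem density, basal
    area, Importance Value Index), quantifies the error of fixed Tier 1
    biomass-to-carbon conversion coefficients against in-situ effective
    carbon fractions, renders per-class stock maps, and ships a seeded
    synthetic-stand generator so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
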