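Package: luccr
Title: Spatially Explicit Land-Use and Cover Change Scenario Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A demand-potential-allocation framework for simulating land-use
    and cover change (LUCC) on regular cellular grids, in the CLUE family of
    models. Linear annual demand trajectories per land-use class and scenario;
    per-cell change-potential surfaces from maximum-likelihood spatial-lag
    regression with Spearman driver screening and AIC model selection;
    iterative demand-constrained allocation with per-cell class competition
    and scenario restriction schedules; multi-resolution map-comparison
    validation (similarity by sampling window, pattern and modified-area fits,
    omission and commission errors); and a synthetic-landscape generator with
    a known spatial-lag data-generating process so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
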