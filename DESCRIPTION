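Package: efnet
Title: Adaptive Executive-Function Assessment Simulation and Psychometric
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates adaptive, classroom-style executive-function (EF)
    assessment batteries over an accelerated longitudinal design and models
    the organization of EF task performance. Provides trial-level generators
    for adaptive response-window and span staircases with known latent
    structure, task metrics (d-prime, rate-correct score, span length, RT
    variability), a task-level quality-control cascade, basic-response-time
    residualization, saturated partial-correlation networks with
    full-information maximum-likelihood moments under missing data, signed
    Spinglass community detection with modal-partition stability, Fisher-z
    network-stability comparisons across cohorts, and confirmatory factor
    analysis of competing one-, two-, and three-factor EF structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
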