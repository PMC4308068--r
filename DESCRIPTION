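Package: epifba
Title: Epistasis Dynamics in Metabolic Networks by Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates genome-scale epistasis dynamics under environmental
    perturbation in constraint-based metabolic models. Computes flux balance
    analysis (FBA), flux variability analysis and geometric FBA solutions,
    builds 50%-flux-restriction single and double mutants, derives epistasis
    and differential-epistasis statistics across iso-growth nutrient-limited
    environments, classifies interactions as stable or dynamic, analyses
    epistasis-network topology, and tests co-evolution of interacting genes
    with resampling. Ships a synthetic-network generator so the whole pipeline
    is testable on small exactly-solvable models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
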