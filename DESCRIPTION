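Package: greytox
Title: Grey Relational Aggregation and Derivative Screening for Multireceptor Ecotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Aggregates per-receptor acute aquatic toxicity values (EC50/LC50,
    mg/L) of a compound panel into a single comprehensive characterization
    score by grey relational analysis against the 1.0 mg/L acute-toxicity
    classification boundary, and screens candidate derivative molecules for
    toxicity remission: change-rate arithmetic, a comprehensive-score increase
    screen, an all-receptor pEC50 reduction screen with proportionality
    diagnostics, functional (stability/insulation/frequency) and persistent
    organic pollutant property verdicts, docking-score comparisons, reaction
    energy barriers, and validators for pharmacophore-model statistics.
    Includes a seeded synthetic-panel generator and a file-based pipeline with
    run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
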