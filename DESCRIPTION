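Package: floresdb
Title: Harmonise Floral Resource Traits and Assess Pollinator Food Supply
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multistep workflow that standardises heterogeneous literature
    records of floral resource traits (phenology, flower density, nectar
    volume, sugar concentration and content, pollen mass or volume, pollen
    protein, corolla depth) to common physical units per floral unit,
    aggregates them on a chosen taxonomic level with explicit imputation
    rules, and computes daily per-area nectar and pollen supply of habitats
    for pollinator habitat assessment. Includes a deterministic synthetic
    fixture generator with an independent straight-line oracle so every
    pipeline stage can be verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
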