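Package: searchrecall
Title: Database-Combination Recall Analysis for Systematic Review Searches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-research on literature-search performance in
    systematic reviews. Given per-review records of which bibliographic
    databases (Embase, MEDLINE, Web of Science, Google Scholar, and others)
    retrieved which references, and which references the published review
    included, the package computes recall, precision, and number needed to
    read for every database combination, attainment distributions across
    reviews, unique-reference contributions per database, and a weighted
    probability model of whether published reviews searched enough databases
    to reach an acceptable recall. A synthetic-corpus generator with a
    ground-truth ledger reproduces the overlap structure of multi-database
    searches so that every stage of the pipeline is testable without access
    to proprietary reference-manager libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
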