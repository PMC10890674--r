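Package: trionet
Title: De Novo Mutation Filtering, Gene Network Search, and Enrichment
    Statistics for Trio Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-trio sequencing studies of neuropsychiatric
    disease. Identifies candidate de novo mutations from per-member read
    counts with a Bayesian genotype model, scores candidates with a
    naive-Bayes log Bayes factor trained on concordant/discordant
    calibration sites, and calibrates the acceptance threshold to a target
    false-positive proportion. Searches a weighted gene-gene phenotypic
    likelihood network for cohesive clusters among variant-hit genes with
    greedy seeded growth and permutation significance. Provides
    hypergeometric/EASE annotation-chart enrichment, variant-type
    composition tests, Venn-overlap statistics, PolyPhen-2 score triage,
    and per-cohort summary tables. A synthetic-data module generates trio
    reads, calibration features, networks, events, and annotation sets
    with known ground truth so every stage is testable end to end.
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
    Matrix,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
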