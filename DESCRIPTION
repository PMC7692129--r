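Package: eqascore
Title: Scoring and Simulation for NGS Proficiency-Testing Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running external quality assessment (EQA) of targeted
    next-generation sequencing in (hemato-)oncology: ingestion of benchmark
    designs and heterogeneous participant variant reports, tolerant parsing and
    canonicalization of protein-level HGVS nomenclature, consensus-based truth
    set classification (evaluative/informative), allele-frequency statistics
    with iterative Grubbs outlier trimming and Z-score citations, panel/cassette
    incompatibility masking, false-negative cause taxonomy, repeatability
    analysis, anonymized global and individual report rendering, and a
    synthetic laboratory-cohort simulator with a planted ground-truth ledger.
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
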