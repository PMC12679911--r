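Package: herdvigor
Title: Sire Prolificacy and Hybrid Vigor Analysis for Multi-Sire Beef Herds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-sire beef cattle breeding programs:
    SNP-exclusion sire verification with panel extension, the Bull
    Prolificacy Index (BPI) per sire and breeding group-year with
    first-21-day correction and quartile stratification, 21-day
    calving-cycle distributions against the 60 percent benchmark, genomic
    vigor scores (retained heterozygosity) from breed composition with dam
    composition back-calculation, retained-daughter cohort productivity
    accounting, and per-10-percent vigor-score trait regressions compared
    to published benchmark constants. Includes a multi-year synthetic herd
    simulator with known ground truth (pedigree, Mendelian genotypes,
    breed compositions, prolificacy weights, injected trait slopes) so
    every stage is testable without producer records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
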