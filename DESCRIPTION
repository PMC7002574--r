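Package: pidnet
Title: Consensus Pathway and Network Prioritization of Coding and
    Non-Coding Cancer Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for prioritizing coding and non-coding cancer
    driver genes from per-element driver p-values. Aggregates element-level
    p-values (coding sequence, core promoter, 5' UTR, 3' UTR, enhancers)
    into gene scores with Fisher's method under missing-element
    degrees-of-freedom reduction, runs an ensemble of pathway and network
    prioritization methods with randomized-data calibration, isolates
    genes whose non-coding signal drives their discovery with a
    permutation-based non-coding value-added (NCVA) test, and combines
    per-method gene sets into consensus driver lists by majority vote.
    Includes degree-preserving network permutation statistics, gene-set
    enrichment tests, in cis mutation-expression association tests, and a
    seeded synthetic-scenario generator with planted drivers so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
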