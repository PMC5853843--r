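Package: ccmshell
Title: Classification and Locus Analysis of Beta-Carboxysome Shell Genes
Version: 0.1.0
Authors@R:
    person("ccmshell", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative genomics of beta-carboxysome shell
    proteins in cyanobacteria. Classifies BMC-H/BMC-T shell proteins
    (CcmK1-6, CcmO) from amino-acid sequence using position-specific
    scoring profiles built from seed alignments, assembles main and
    satellite carboxysome loci from ordinal gene tables using adjacency
    gap rules, quantifies class co-occurrence across a genome cohort with
    observed/expected ratios and chi-squared tests, and measures
    co-regulation of shell genes with the main carboxysome locus from
    expression matrices. Includes a synthetic-data generator emulating
    beta-cyanobacterial genome architectures, class-specific sequence
    families and block-correlated expression so that every pipeline stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
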