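Package: mosaicscreen
Title: Phylogenomic Screening for Lateral and Endosymbiotic Gene Transfer in Euglenid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable phylogenomic screen for genome mosaicism in euglenids
    and other secondary algae. For each gene family the pipeline trims indel-rich
    alignment columns and taxa, builds a bootstrapped neighbor-joining tree from
    corrected protein distances, collapses single-genus clades, reports the
    lineage group patristically closest to a designated query sequence, and
    classifies the gene tree into endosymbiotic/lateral-transfer topology
    categories (CR+Red, CR+Green, red-lineage/other) using explicit bootstrap
    and posterior support thresholds. A scenario simulator plants vertical,
    green endosymbiotic, and red-lineage transfer histories into gene families
    so every stage is testable without external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
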