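Package: hepityper
Title: Targeted Bisulfite Amplicon Sequencing and Hepitype Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for targeted bisulfite amplicon
    sequencing of DNA methylation. Designs redundant PCR primer panels on
    in-silico bisulfite-converted target DNA (segmentation, nearest-neighbor
    melting temperatures, variant and CpG masking, in-silico PCR off-target
    screening, coverage-driven selection with melting-temperature
    relaxation), maps reads to ambiguity-coded amplicons with approximate
    primer matching and dynamic-programming alignment, quantifies per-CpG
    methylation with coverage and polymorphism flags, and phases
    read-level methylation patterns ("hepitypes") into frequency spectra,
    unrooted maximum-parsimony trees with bootstrap support, and a
    deviating-site exact test for methylation-maintenance asymmetry. A
    seeded simulator generates reference sequences, clonal methylation
    mixtures, bisulfite conversion with configurable efficiency, and
    sequencing reads for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
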