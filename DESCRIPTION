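Package: mitocomp
Title: Comparative Analysis of Vertebrate Mitochondrial Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for desk-scale comparative mitogenomics: homology-transfer
    annotation of circular mitochondrial genomes with majority-rule consensus
    over reference placements, feature-table arithmetic and validation,
    control-region domain and motif (TAS/CSB) partitioning, gap-weighted
    p-distances and the distance-regression relative-rate estimator against a
    reference rRNA, normalized codon-usage matrices with Lance-Williams
    agglomerative clustering, sliding-window amino-acid-scale accessibility
    profiles of protein termini, and a sequence-evolution simulator (HKY/JC
    with per-partition rate multipliers and a control-region indel process)
    that provides known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
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
    utils
Suggests:
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
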