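Package: gsforge
Title: Contrast-Data Management, Gene-Set Extraction and Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A workbench for managing omics contrast statistics and the gene
    sets derived from them. Parses and writes the idMAPS tab-delimited format
    (metadata header plus repeating M/A/P/S column groups per contrast), maps
    source identifiers (probe sets, gene symbols, Entrez IDs) to a
    gene-centric ID space using RefSeq curation status to pick best genes,
    collapses multi-probe measurements under several strategies, extracts
    up-/down-/all-regulated (UP/DN/AR) gene sets under configurable
    thresholds into a versioned on-disk knowledge base, and analyses ranked
    or differentially-expressed gene lists by preranked gene set enrichment
    analysis (weighted Kolmogorov-Smirnov running statistic with a
    gene-permutation null) or hypergeometric over-representation analysis
    with Benjamini-Hochberg FDR control. Includes leading-edge and
    cross-contrast results-matrix post-processing, GMT import/export,
    membership and overlap matrices, seeded synthetic-data generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
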