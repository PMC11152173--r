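Package: rriclass
Title: Classification of Biologically Relevant RNA-RNA Interaction Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A trainable pipeline that decides whether putative RNA-RNA
    interaction (RRI) sites from direct-duplex-detection interactome
    experiments are biologically relevant. Curates reliable sites from
    replicated interaction tables by overlap concordance and score
    filtering, predicts seed-anchored intermolecular duplexes under
    occupancy constraints with a dynamic program, constructs context-local
    negative instances, engineers sequence, interaction and
    Weisfeiler-Lehman graph-kernel features, selects a tree-ensemble
    classifier by randomized search, and evaluates new candidate sites.
    Includes a synthetic interactome generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    Matrix,
    Rcpp,
    ranger,
    xgboost,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
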