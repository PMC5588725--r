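Package: maxsnippet
Title: Max-Snippet Classification of Immune Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnose patients from B-cell receptor repertoires by decomposing
    every CDR3 into overlapping k-mer snippets, scoring each snippet with a
    logistic detector over biochemical (Atchley-factor) features, and taking
    the maximum snippet score as the repertoire-level diagnosis probability.
    Detector parameters are fit by maximum likelihood with batched Adam
    gradient descent and random restarts. Includes leave-one-out
    cross-validation for model selection, a label-permutation significance
    test, ROC analysis, motif interpretation tools, codon encoding-degeneracy
    analysis, sequence preprocessing filters, and a synthetic-cohort
    generator with planted motifs so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Rcpp,
    methods,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
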