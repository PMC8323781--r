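Package: raacpred
Title: Protein Family Classification with Reduced Amino Acid Alphabets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-class protein family classifier built on reduced amino acid
    cluster (RAAC) encodings. Protein sequences are rewritten over a reduced
    alphabet, encoded as k-mer composition vectors, ranked by one-way ANOVA
    F-scores, pruned by incremental feature selection, and classified with a
    grid-searched RBF-kernel support vector machine under stratified k-fold
    cross-validation. Ships the 18 nested type-33 reduction schemes (sizes
    2-19), a scan over (scheme, k) encodings, full evaluation metrics
    (sensitivity, specificity, F1, accuracy, Matthews correlation, ROC/AUC),
    and a seeded synthetic-data generator that plants a conserved
    HxD...H-style metal-binding motif in positive sequences so the entire
    pipeline is testable without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
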