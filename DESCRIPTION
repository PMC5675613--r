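Package: mirdiff
Title: MicroRNA-Disease Association Prediction by Expression-Based Two-Way Network Diffusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate microRNA-disease associations from known
    association lists, microRNA expression profiles across human tissues, and
    MeSH-style disease term hierarchies. MicroRNA similarity is the Pearson
    correlation of expression profiles (with a mean-imputation rule for
    microRNAs lacking profiles); disease similarity is a decay-weighted
    semantic similarity on each disease's directed acyclic graph of ancestor
    terms. Scores come from a three-step two-way resource-diffusion scheme on
    two similarity-weighted copies of the bipartite association network.
    Includes leave-one-out and repeated k-fold cross-validation harnesses with
    rank-concordance AUC, collaborative-filtering and Katz-index baselines, a
    synthetic-data generator with planted cluster structure, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
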