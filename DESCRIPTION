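Package: siamdr
Title: Drug Repurposing with Knowledge-Graph Embeddings and Siamese Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds typed drug-disease knowledge graphs from tabular node and
    edge lists, embeds their entities and relations with a continuous
    bag-of-words model trained on triplet sentences, and scores drug-disease
    therapeutic associations with a dual-channel (siamese) neural network
    whose drug and disease channels may have independent (heterogeneous) or
    shared (homogeneous) weights. Includes adverse-reaction negative
    sampling, class-imbalance strategies (random under/over-sampling, SMOTE
    and a SMOTE-then-undersample combination), binary-classifier metrics
    (accuracy, AUC-ROC, AUC-PR, Brier score, Matthews correlation, F1),
    a repeated cross-validation harness, a synthetic benchmark generator
    with planted cluster signal, and an end-to-end pipeline with an
    ablation grid over graph versions, weight modes and imbalance
    strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
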