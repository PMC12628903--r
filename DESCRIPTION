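Package: ppifusion
Title: Protein-Protein Interaction Prediction from Fused Protein
    Language Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts physical protein-protein interactions from
    sequence embeddings. Per-residue embedding matrices from two protein
    language models (1536- and 1280-dimensional) are mean-pooled and
    concatenated into a 2816-dimensional vector per protein; pairs are
    fused through a shared-weight extraction layer, scaled dot-product
    self-attention over the two proteins, and an element-wise mean
    branch, then classified by a deep neural network with an optional
    multi-head attention block and a sigmoid output. Includes the
    STRING-based dataset construction pipeline (score labeling, length
    filtering, greedy sequence-identity clustering, negative
    subsampling), binary cross-entropy/Adam training with early stopping
    and five-fold cross-validation, threshold and ranking metrics
    (sensitivity, precision, F1, MCC, AUPR, AUC), a deterministic
    synthetic embedder, and synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    knitr,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
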