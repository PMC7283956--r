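Package: mandti
Title: Drug-Target Interaction Prediction from Molecular Association
    Networks by Random-Walk Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTIs) by embedding every
    node of a heterogeneous molecular associations network (drugs,
    proteins, diseases, lncRNAs, miRNAs linked by nine association types)
    with truncated uniform random walks and a skip-gram model (DeepWalk).
    The learned "behavior" vectors are compared against sequence- and
    structure-derived "attribute" features (reduced-alphabet 3-mer protein
    composition, substructure fingerprint bit-vectors) under stratified
    k-fold cross-validation with pluggable classifiers, reporting
    accuracy, sensitivity, specificity, precision, Matthews correlation
    and ROC-AUC. Includes a seedable planted-partition generator of
    synthetic networks, protein sequences and fingerprints so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    randomForest,
    e1071,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
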