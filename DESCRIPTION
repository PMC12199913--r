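Package: nmpred
Title: Moment-Based Sequence Features and Ensemble Classifiers for RNA
    2'-O-Methylation Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes fixed 41-nucleotide RNA windows centred on a candidate
    2'-O-methylation (Nm) site into 522-dimensional feature vectors built
    from positional k-mer descriptors (position-relative incidence matrices,
    frequency and accumulative-position vectors, a near-square 2-D sequence
    matrix) reduced through raw, central and orthonormal discrete Hahn
    moments of degree at most three.  Provides a registry of bagging and
    boosting ensemble classifiers plus conventional baselines over these
    features, stratified independent-test and k-fold cross-validation
    protocols with sensitivity, specificity, accuracy, Matthews correlation
    and ROC/AUC reporting, a synthetic benchmark generator emulating
    nucleotide-specific Nm datasets, and a command-line interface for
    simulation, encoding, training, evaluation and genome-scan prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    ranger,
    rpart,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
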