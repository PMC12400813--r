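Package: scSwarmLDA
Title: Cell Type Annotation with Swarms of Penalized Linear Discriminant Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised cell-type annotation for single-cell RNA-seq data.
    Trains an ensemble (swarm) of closed-form penalized linear discriminant
    analysis models on random cell/gene subsets of a labelled reference,
    combines their discriminant scores through small per-model prediction
    networks and a softmax-weighted per-class voting layer, and trains the
    combination jointly with a combined cross-entropy loss. Includes the
    standard preprocessing pipeline (quality control, log-normalization,
    Wilcoxon rank-sum marker screening), a negative-binomial count simulator
    for testing, evaluation utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
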