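Package: LACFNForest
Title: Laminar Augmented Cascading Flexible Neural Forests for Expression-Based Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classification of cancer subtypes and other multi-class phenotypes
    from high-dimensional, small-sample gene-expression matrices using flexible
    neural trees (FNTs). Tree structures are evolved by grammar-guided genetic
    programming and their weights tuned by particle swarm optimization; trees
    are composed into M-ary binary-task forests (DFNForests) that deepen by
    cascaded feature augmentation, and DFNForests are ensembled into a
    layer-by-layer widening laminar model with confidence-gated early exit,
    densely connected feature augmentation, and triangular layer weighting.
    Includes expression-matrix preprocessing (missingness filtering, KNN
    imputation, z-score normalization), a synthetic-data generator for
    expression-like benchmarks, and stratified cross-validation with macro
    precision/recall/F1 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table,
    caret,
    SummarizedExperiment,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, GeneExpression, Transcriptomics
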