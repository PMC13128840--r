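Package: sctwin
Title: Self-Supervised Twin-View Feature Decorrelation for Single-Cell
    Data Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates multi-batch single-cell RNA-seq data by
    negative-sample-free self-supervised representation learning. Two
    stochastically distorted views of each expression profile are embedded
    by a Siamese dense multilayer perceptron whose normalization layers
    hold domain-specific statistics; a cross-correlation objective pushes
    matching embedding dimensions of the two views towards perfect
    correlation while decorrelating distinct dimensions, computed and
    averaged per domain so that batches are aligned implicitly. Includes a
    seeded negative-binomial multi-batch count simulator, the preprocessing
    pipeline (gene filtering, depth normalization, per-batch highly
    variable gene selection), integration benchmarking metrics (ARI, NMI,
    silhouette scores, graph connectivity, batch mixing entropy,
    overcorrection) with min-max score aggregation, and leave-one-batch-out
    kNN label transfer evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    cluster,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
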