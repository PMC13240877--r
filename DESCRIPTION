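Package: spotempo
Title: Density-Adaptive Optimal-Transport Trajectory Inference for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory inference for spatial transcriptomics. Builds an
    alpha-complex spatial neighborhood graph from spot coordinates, learns a
    joint gene-and-space embedding with a masked feature encoder and a
    variational graph autoencoder, fuses embedding distances with raw spatial
    distances under a cell-density-adaptive weighting with low-confidence
    protection, and derives cell-cell transition matrices by entropy-regularized
    optimal transport (log-domain Sinkhorn). From the transition matrix it
    computes pseudotime by probability accumulation from user-specified start
    cells, least-action lineage paths, per-cell velocity vectors with grid
    interpolation and streamlines, and pseudotime-dependent gene trends. A
    multi-section mode runs per-section inference in a shared PCA/UMAP
    embedding. Includes a synthetic spatial-trajectory simulator with
    ground-truth developmental time for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    matrixStats,
    deldir,
    igraph,
    mgcv,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    uwot,
    irlba,
    RANN,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
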