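Package: scAFTV
Title: Adaptive Fractional-Order Total-Variation Low-Rank Representation
    for Single-Cell Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns a nonnegative low-rank cell-cell coefficient matrix from a
    single-cell RNA-seq expression matrix under an adaptive fractional-order
    total-variation (Grunwald-Letnikov) regulariser, solved by ADMM with
    singular value thresholding, and clusters cells by spectral clustering on
    the symmetrised similarity matrix. Includes gene filtering and
    normalisation, ARI/NMI evaluation of partitions, one-vs-rest marker-gene
    ranking by Welch t statistics, and a seeded generator of dropout-sparse,
    cluster-structured synthetic expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
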