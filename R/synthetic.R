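#' Simulate dropout-sparse, cluster-structured expression data
#'
#' Generates a genes x cells matrix under the union-of-subspaces model the
#' method targets: each cluster c has its own nonnegative low-dimensional
#' basis B_c (n_genes x latentDim) and every cell of the cluster is a
#' nonnegative combination of that basis, so the clean signal has rank at
#' most `nClusters * latentDim`. Cluster specificity is modelled as gene
#' programs: each gene is assigned to one cluster's program and loads with
#' `signalScale` in that cluster's basis and `0.35 * signalScale` elsewhere
#' (programs are enriched, not exclusive, as pathway genes are in real
#' data). The first `markersPerCluster` program genes of each cluster are
#' the exception: they are cluster-exclusive markers, loading at only
#' `0.02 * signalScale` outside their cluster and additively boosted by
#' `markerBoost` on their own basis rows (inside the cluster subspace, so
#' the rank bound is preserved).
#' Technical corruption is applied on top: multiplicative log-normal noise
#' `exp(noiseSigma * N(0,1))` per entry, then Bernoulli dropout zeroing each
#' entry independently with probability `dropoutRate`. With
#' `countData = TRUE` the noisy signal is converted to integer counts by a
#' Poisson draw (for testing count preprocessing); otherwise values stay
#' continuous on a post-normalisation scale.
#'
#' @param nClusters number of clusters (>= 1).
#' @param cellsPerCluster cells per cluster: a single integer or one per
#'   cluster (each >= 2).
#' @param nGenes number of genes.
#' @param latentDim per-cluster subspace dimension (default 3).
#' @param signalScale scale of the basis entries (default 1).
#' @param noiseSigma multiplicative log-normal noise width (default 0.1).
#' @param dropoutRate Bernoulli zeroing probability in [0, 1) (default 0.3).
#' @param markersPerCluster genes boosted exclusively in one cluster
#'   (default 5); the total across clusters must not exceed `nGenes`.
#' @param markerBoost additive boost applied to marker basis rows
#'   (default `5 * signalScale`).
#' @param seed RNG seed; identical seeds give identical output.
#' @param countData return integer Poisson counts instead of continuous
#'   values (default FALSE).
#' @return a [SingleCellExperiment::SingleCellExperiment] with one assay
#'   `"expr"` (genes x cells, nonnegative) and the ground-truth cluster in
#'   `colData(.)$cluster` (factor `C1`, `C2`, ...).
#' @examples
#' sce <- simulateCells(nClusters = 2, cellsPerCluster = 5, nGenes = 40, seed = 7)
#' dim(sce)
#' table(SummarizedExperiment::colData(sce)$cluster)
#' @export
simulateCells <- function(nClusters = 3, cellsPerCluster = 30, nGenes = 200,
                          latentDim = 3, signalScale = 1, noiseSigma = 0.1,
                          dropoutRate = 0.3, markersPerCluster = 5,
                          markerBoost = 5 * signalScale, seed = 1,
                          countData = FALSE) {
  stopifnot(nClusters >= 1, nGenes >= 1, latentDim >= 1, signalScale > 0,
            noiseSigma >= 0, dropoutRate >= 0, dropoutRate < 1,
            markersPerCluster >= 0)
  if (length(cellsPerCluster) == 1) {
    cellsPerCluster <- rep(cellsPerCluster, nClusters)
  }
  if (length(cellsPerCluster) != nClusters || any(cellsPerCluster < 2)) {
    stop("cellsPerCluster must give >= 2 cells for each of the ",
         nClusters, " clusters")
  }
  if (markersPerCluster * nClusters > nGenes) {
    stop("markersPerCluster * nClusters exceeds the gene count")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  n <- sum(cellsPerCluster)
  labels <- factor(rep(paste0("C", seq_len(nClusters)), cellsPerCluster))
  ## gene programs (round-robin assignment): a program gene loads fully on
  ## its own cluster's basis and partially (35%) elsewhere, so subspaces are
  ## distinct but genes are shared; markers (the first genes of each
  ## program) are the only cluster-EXCLUSIVE genes - near-zero loading
  ## outside their cluster plus an additive boost on their basis rows
  program <- rep_len(seq_len(nClusters), nGenes)
  isMarker <- rep(FALSE, nGenes)
  if (markersPerCluster > 0) {
    for (c in seq_len(nClusters)) {
      isMarker[which(program == c)[seq_len(markersPerCluster)]] <- TRUE
    }
  }
  X <- matrix(0, nGenes, n)
  offset <- 0L
  for (c in seq_len(nClusters)) {
    own <- program == c
    load <- ifelse(own, signalScale,
                   ifelse(isMarker, 0.02, 0.35) * signalScale)
    B <- matrix(abs(rnorm(nGenes * latentDim)), nGenes, latentDim) * load
    if (markersPerCluster > 0) {
      B[own & isMarker, ] <- B[own & isMarker, ] + markerBoost
    }
    nc <- cellsPerCluster[c]
    coeff <- matrix(runif(latentDim * nc, 0.2, 1), latentDim, nc)
    X[, offset + seq_len(nc)] <- B %*% coeff
    offset <- offset + nc
  }
  if (noiseSigma > 0) {
    X <- X * exp(noiseSigma * matrix(rnorm(length(X)), nrow(X)))
  }
  if (countData) X <- matrix(rpois(length(X), X), nrow(X))
  if (dropoutRate > 0) {
    X <- X * matrix(rbinom(length(X), 1, 1 - dropoutRate), nrow(X))
  }
  ## real matrices are not sorted by cell type: shuffle the cell order so
  ## that column adjacency carries no label information (the grid
  ## regulariser must not be able to read the clustering off the layout)
  perm <- sample.int(n)
  X <- X[, perm, drop = FALSE]
  labels <- labels[perm]
  dimnames(X) <- list(paste0("gene_", seq_len(nGenes)),
                      paste0("cell_", seq_len(n)))
  markerList <- if (markersPerCluster > 0) {
    stats::setNames(
      lapply(seq_len(nClusters), function(c) {
        rownames(X)[which(program == c)[seq_len(markersPerCluster)]]
      }),
      paste0("C", seq_len(nClusters))
    )
  } else {
    list()
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(expr = X),
    colData = S4Vectors::DataFrame(cluster = labels,
                                   row.names = colnames(X)),
    metadata = list(markers = markerList, seed = seed)
  )
}

#' Canonical synthetic test fixture
#'
#' The reference simulation used throughout the test suite: 3 clusters of 30
#' cells, 200 genes, 3-dimensional cluster subspaces, log-normal noise width
#' 0.1, 30% dropout, 5 planted markers per cluster, seed 1. The clean
#' variant (`clean = TRUE`) turns noise and dropout off, leaving exactly
#' separable subspace data.
#'
#' @param clean disable noise and dropout (default FALSE).
#' @param seed RNG seed (default 1).
#' @return a [SingleCellExperiment::SingleCellExperiment]; see
#'   [simulateCells()].
#' @export
standardFixture <- function(clean = FALSE, seed = 1) {
  simulateCells(
    nClusters = 3, cellsPerCluster = 30, nGenes = 200, latentDim = 3,
    signalScale = 1, noiseSigma = if (clean) 0 else 0.1,
    dropoutRate = if (clean) 0 else 0.3, markersPerCluster = 5, seed = seed
  )
}
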