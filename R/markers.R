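#' Rank cluster marker genes by Welch t statistics
#'
#' For every cluster, computes for each gene the two-sample Welch t statistic
#' (unequal variances) between the cells of that cluster and all remaining
#' cells, on the same preprocessed matrix that was fed to the model. Genes
#' are ranked per cluster by decreasing |t| and the top `topN` kept. Per-group
#' variances are floored at `varFloor` so genes that are constant within a
#' group get a finite score.
#'
#' @param X preprocessed genes x cells matrix (or SummarizedExperiment,
#'   first assay) with gene identifiers as rownames.
#' @param labels cluster label per cell (length `ncol(X)`); every cluster
#'   must have at least 2 cells.
#' @param topN markers kept per cluster (default 25); truncated to the gene
#'   count when larger.
#' @param varFloor variance floor (default 1e-8).
#' @return data.frame with columns `cluster`, `rank`, `gene`, `t_score`
#'   (signed; positive = higher in cluster), `mean_in`, `mean_out`, sorted by
#'   cluster then decreasing |t|.
#' @export
rankMarkerGenes <- function(X, labels, topN = 25, varFloor = 1e-8) {
  if (is(X, "SummarizedExperiment")) X <- SummarizedExperiment::assay(X, 1)
  X <- as.matrix(X)
  if (length(labels) != ncol(X)) stop("labels must match the cell count")
  if (topN < 1) stop("topN must be >= 1")
  if (is.null(rownames(X))) rownames(X) <- paste0("gene_", seq_len(nrow(X)))
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 clusters to rank markers")
  if (any(sizes < 2)) {
    stop("every cluster needs at least 2 cells; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  topN <- min(topN, nrow(X))
  res <- lapply(sort(names(sizes)), function(cl) {
    inC <- labels == cl
    n1 <- sum(inC)
    n2 <- sum(!inC)
    Xin <- X[, inC, drop = FALSE]
    Xout <- X[, !inC, drop = FALSE]
    m1 <- rowMeans(Xin)
    m2 <- rowMeans(Xout)
    v1 <- pmax(rowSums((Xin - m1)^2) / (n1 - 1), varFloor)
    v2 <- pmax(rowSums((Xout - m2)^2) / (n2 - 1), varFloor)
    t <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
    ord <- order(abs(t), decreasing = TRUE)[seq_len(topN)]
    data.frame(
      cluster = cl, rank = seq_len(topN), gene = rownames(X)[ord],
      t_score = t[ord], mean_in = m1[ord], mean_out = m2[ord],
      row.names = NULL
    )
  })
  do.call(rbind, res)
}

#' Write a marker table to TSV
#'
#' @param markers output of [rankMarkerGenes()].
#' @param path output TSV path.
#' @export
writeMarkerTable <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
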