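## Preprocessing: gene filtering, log transform, library-size normalisation,
## per-cell L2 normalisation. All functions are generic with methods for
## plain matrices (genes x cells) and SummarizedExperiment (first assay).

.checkExprMatrix <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("expression matrix must be finite")
  X
}

## wrap a matrix-method result back into the SummarizedExperiment container,
## subsetting rows if the gene set changed
.seApply <- function(se, fun, ...) {
  X <- SummarizedExperiment::assay(se, 1)
  Y <- fun(as.matrix(X), ...)
  if (!identical(rownames(Y), rownames(X))) {
    se <- se[match(rownames(Y), rownames(X)), ]
  }
  SummarizedExperiment::assay(se, 1) <- Y
  for (a in c("removed", "filterThreshold")) {
    at <- attr(Y, a, exact = TRUE)
    if (!is.null(at)) S4Vectors::metadata(se)[[a]] <- at
  }
  se
}

#' Filter genes by zero fraction
#'
#' Removes genes whose fraction of zero entries across cells strictly exceeds
#' `threshold` (default 0.95: a gene is dropped only when more than 95% of
#' its values are zero). Cell order is preserved; the identifiers of removed
#' genes are recorded in the `"removed"` attribute (metadata for
#' SummarizedExperiment input).
#'
#' @param X genes x cells matrix, or a SummarizedExperiment.
#' @param threshold zero-fraction cutoff in [0, 1].
#' @return the filtered object; errors if no gene survives.
#' @export
setGeneric("filterGenes", function(X, threshold = 0.95) {
  standardGeneric("filterGenes")
})

#' @rdname filterGenes
#' @export
setMethod("filterGenes", "matrix", function(X, threshold = 0.95) {
  stopifnot(threshold >= 0, threshold <= 1)
  X <- .checkExprMatrix(X)
  zf <- rowMeans(X == 0)
  keep <- zf <= threshold
  if (!any(keep)) stop("all genes filtered at threshold ", threshold)
  out <- X[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(X)[!keep]
  attr(out, "filterThreshold") <- threshold
  out
})

#' @rdname filterGenes
#' @export
setMethod("filterGenes", "SummarizedExperiment", function(X, threshold = 0.95) {
  .seApply(X, function(M) filterGenes(M, threshold))
})

#' Log2 transform with pseudo-count 1
#'
#' Replaces every entry x by `log2(x + 1)`. Exposed as a standalone
#' transform; the default pipeline uses [normalizeCounts()], which already
#' contains the log, so the two are not composed by default.
#'
#' @param X genes x cells matrix, or a SummarizedExperiment.
#' @return transformed object, same shape.
#' @export
setGeneric("logTransform", function(X) standardGeneric("logTransform"))

#' @rdname logTransform
#' @export
setMethod("logTransform", "matrix", function(X) {
  X <- .checkExprMatrix(X)
  if (min(X) < 0) stop("negative values; logTransform expects nonnegative input")
  log2(X + 1)
})

#' @rdname logTransform
#' @export
setMethod("logTransform", "SummarizedExperiment", function(X) {
  .seApply(X, logTransform)
})

#' Library-size normalisation
#'
#' Each entry becomes `log2(x_ij / colsum_j * scaleFactor + 1)` where
#' `colsum_j` is the total of cell j in the input to this call. The result is
#' exactly invariant to rescaling any cell by a positive constant. All-zero
#' cells are left all-zero with a warning.
#'
#' @param X genes x cells matrix, or a SummarizedExperiment.
#' @param scaleFactor positive scale (default 1e5).
#' @return normalised object, same shape.
#' @export
setGeneric("normalizeCounts", function(X, scaleFactor = 1e5) {
  standardGeneric("normalizeCounts")
})

#' @rdname normalizeCounts
#' @export
setMethod("normalizeCounts", "matrix", function(X, scaleFactor = 1e5) {
  stopifnot(scaleFactor > 0)
  X <- .checkExprMatrix(X)
  if (min(X) < 0) stop("negative values; normalizeCounts expects nonnegative input")
  cs <- colSums(X)
  zero <- cs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell column(s) left unnormalised")
    cs[zero] <- 1
  }
  log2(sweep(X, 2, cs, "/") * scaleFactor + 1)
})

#' @rdname normalizeCounts
#' @export
setMethod("normalizeCounts", "SummarizedExperiment",
  function(X, scaleFactor = 1e5) .seApply(X, normalizeCounts, scaleFactor)
)

#' Per-cell L2 normalisation
#'
#' Divides each cell column by its Euclidean norm, removing scale differences
#' between cells; all-zero columns are left unchanged.
#'
#' @param X genes x cells matrix, or a SummarizedExperiment.
#' @return normalised object, same shape; every nonzero column has unit norm.
#' @export
setGeneric("l2NormalizeCells", function(X) standardGeneric("l2NormalizeCells"))

#' @rdname l2NormalizeCells
#' @export
setMethod("l2NormalizeCells", "matrix", function(X) {
  X <- .checkExprMatrix(X)
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  sweep(X, 2, nrm, "/")
})

#' @rdname l2NormalizeCells
#' @export
setMethod("l2NormalizeCells", "SummarizedExperiment", function(X) {
  .seApply(X, l2NormalizeCells)
})

#' Default preprocessing pipeline
#'
#' Composes the standard steps in the order the model expects:
#' gene filtering (zero fraction > `threshold` removed), library-size
#' normalisation with log (on the filtered matrix, so the column sums the
#' model sees are the filtered ones), then per-cell L2 normalisation.
#' The standalone [logTransform()] is not applied on top of
#' [normalizeCounts()], which already contains the log.
#'
#' @param X genes x cells matrix, or a SummarizedExperiment.
#' @param threshold zero-fraction gene filter cutoff (default 0.95).
#' @param scaleFactor library-size scale (default 1e5).
#' @param countScaling apply [normalizeCounts()] (default TRUE).
#' @param l2 apply [l2NormalizeCells()] (default TRUE).
#' @return preprocessed object of the same class as the input.
#' @export
preprocessCells <- function(X, threshold = 0.95, scaleFactor = 1e5,
                            countScaling = TRUE, l2 = TRUE) {
  X <- filterGenes(X, threshold)
  if (countScaling) X <- normalizeCounts(X, scaleFactor)
  if (l2) X <- l2NormalizeCells(X)
  X
}
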