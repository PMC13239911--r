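## k-means++ seeding: first center uniform, later centers sampled with
## probability proportional to squared distance to the nearest chosen center.
## Rows already chosen (distance 0) get weight 0, keeping centers distinct.
.kmeansppCenters <- function(E, k) {
  n <- nrow(E)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- colSums((t(E) - E[centers[1], ])^2)
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        ## fewer distinct rows than centers still needed: fall back to the
        ## remaining unused rows (duplicates are centre-equivalent anyway)
        left <- setdiff(seq_len(n), centers[seq_len(j - 1)])
        centers[j] <- left[1]
      } else {
        centers[j] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, colSums((t(E) - E[centers[j], ])^2))
    }
  }
  E[centers, , drop = FALSE]
}

#' Spectral clustering of a similarity matrix
#'
#' Normalised spectral clustering in the Ng-Jordan-Weiss form: from the
#' symmetric nonnegative similarity S, build the degree vector d (row sums,
#' floored at a tiny positive constant for isolated cells), the symmetric
#' normalised Laplacian `L = I - D^{-1/2} S D^{-1/2}`, take the eigenvectors
#' of its k smallest eigenvalues, row-normalise that spectral embedding, and
#' partition the rows by k-means with `nRestarts` k-means++-seeded restarts
#' under `seed` (the restart with the lowest within-cluster sum wins).
#'
#' @param S symmetric nonnegative n x n similarity matrix (or an
#'   [AFTVFit-class], whose similarity matrix is used).
#' @param k number of clusters, 1 <= k <= n.
#' @param seed RNG seed making the k-means restarts reproducible.
#' @param nRestarts number of seeded k-means restarts (default 30).
#' @return a [SpectralClustering-class] with labels in 1..k and the smallest
#'   k + 1 Laplacian eigenvalues.
#' @examples
#' S <- as.matrix(Matrix::bdiag(matrix(1, 3, 3), matrix(1, 4, 4)))
#' clusterLabels(spectralClustering(S, 2))
#' @export
spectralClustering <- function(S, k, seed = 1L, nRestarts = 30L) {
  if (is(S, "AFTVFit")) S <- similarityMatrix(S)
  S <- as.matrix(S)
  n <- nrow(S)
  if (ncol(S) != n) stop("S must be square")
  if (any(!is.finite(S))) stop("S contains non-finite entries")
  if (max(abs(S - t(S))) > 1e-8 * (max(abs(S)) + 1)) {
    stop("S is not symmetric")
  }
  if (k < 1 || k > n) stop("k must be between 1 and ncol(S)")
  S <- (S + t(S)) / 2
  d <- pmax(rowSums(S), 1e-12)
  isq <- 1 / sqrt(d)
  L <- diag(n) - isq * sweep(S, 2, isq, "*")
  eg <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- seq(n, n - k + 1)            # eigen() sorts decreasing; take smallest
  E <- eg$vectors[, ord, drop = FALSE]
  rn <- sqrt(rowSums(E^2))
  rn[rn == 0] <- 1
  E <- E / rn
  evals <- rev(eg$values)[seq_len(min(k + 1, n))]
  # trivial partitions: one cluster, or one cluster per cell
  if (k == 1 || k == n) {
    labs <- if (k == 1) rep(1L, n) else seq_len(n)
    return(new("SpectralClustering",
      labels = labs, k = as.integer(k), seed = as.integer(seed),
      eigenvalues = evals
    ))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(max(1L, nRestarts))) {
    km <- suppressWarnings(
      stats::kmeans(E, centers = .kmeansppCenters(E, k), iter.max = 100)
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  new("SpectralClustering",
    labels = as.integer(best$cluster), k = as.integer(k),
    seed = as.integer(seed), eigenvalues = evals
  )
}
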