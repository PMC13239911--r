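#' Contingency table of two partitions
#'
#' Counts n_ij of items with reference class i and predicted class j, the
#' shared basis of the Rand-type and information-theoretic agreement scores.
#'
#' @param truth,pred equal-length label vectors (any atomic type).
#' @return integer matrix with reference classes in rows and predicted
#'   classes in columns; `sum(.) == length(truth)`.
#' @export
contingencyTable <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  if (!length(truth)) stop("empty label vectors")
  unclass(table(truth = as.character(truth), pred = as.character(pred)))
}

#' Normalised mutual information between two partitions
#'
#' `2 I(X;Y) / (H(X) + H(Y))` with entropies of the empirical label
#' proportions (natural log; the base cancels). If both partitions are the
#' trivial single cluster (H(X) + H(Y) = 0) the partitions are identical and
#' 1 is returned.
#'
#' @inheritParams contingencyTable
#' @return a number in [0, 1].
#' @examples
#' clusterNMI(c(0, 0, 1, 1), c(0, 1, 0, 1)) # independent: 0
#' @export
clusterNMI <- function(truth, pred) {
  ct <- contingencyTable(truth, pred)
  n <- sum(ct)
  pij <- ct / n
  pi. <- rowSums(pij)
  p.j <- colSums(pij)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hx <- ent(pi.)
  hy <- ent(p.j)
  if (hx + hy == 0) return(1)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi., p.j)[nz]))
  2 * mi / (hx + hy)
}

#' Rand index between two partitions
#'
#' `(a + b) / choose(n, 2)` where a counts item pairs placed together in both
#' partitions and b pairs separated in both.
#'
#' @inheritParams contingencyTable
#' @return a number in [0, 1].
#' @export
randIndex <- function(truth, pred) {
  ct <- contingencyTable(truth, pred)
  n <- sum(ct)
  if (n < 2) stop("need at least 2 items")
  a <- sum(choose(ct, 2))
  sumA <- sum(choose(rowSums(ct), 2))
  sumB <- sum(choose(colSums(ct), 2))
  b <- choose(n, 2) - sumA - sumB + a
  (a + b) / choose(n, 2)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair agreement `(RI - E[RI]) / (max(RI) - E[RI])` in its
#' standard contingency form. In the degenerate case where the correction
#' denominator is zero (e.g. both partitions trivial), returns 1 when the
#' partitions are identical and 0 otherwise.
#'
#' @inheritParams contingencyTable
#' @return a number in [-1, 1]; 1 for identical partitions (up to label
#'   renaming).
#' @examples
#' clusterARI(c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 1, 1, 1)) # 1.2 / 3.7
#' @export
clusterARI <- function(truth, pred) {
  ct <- contingencyTable(truth, pred)
  n <- sum(ct)
  if (n < 2) stop("need at least 2 items")
  sumIJ <- sum(choose(ct, 2))
  sumA <- sum(choose(rowSums(ct), 2))
  sumB <- sum(choose(colSums(ct), 2))
  expIJ <- sumA * sumB / choose(n, 2)
  denom <- (sumA + sumB) / 2 - expIJ
  if (denom == 0) {
    same <- clusterNMI(truth, pred) == 1 &&
      nrow(ct) == ncol(ct) && all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
    return(if (same) 1 else 0)
  }
  (sumIJ - expIJ) / denom
}

#' Partition agreement report
#'
#' Convenience wrapper returning ARI, NMI and the raw Rand index together.
#'
#' @inheritParams contingencyTable
#' @return named list with elements `ari`, `nmi`, `rand_index` and the
#'   contingency table.
#' @export
clusterMetrics <- function(truth, pred) {
  list(
    ari = clusterARI(truth, pred),
    nmi = clusterNMI(truth, pred),
    rand_index = randIndex(truth, pred),
    contingency = contingencyTable(truth, pred)
  )
}
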