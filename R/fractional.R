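#' Grunwald-Letnikov coefficients
#'
#' Signed generalised-binomial weights
#' \eqn{w_k = (-1)^k \Gamma(\beta+1) / (\Gamma(k+1)\Gamma(\beta+1-k))},
#' k = 0..K-1, computed through the exact recurrence
#' \eqn{\binom{\beta}{k} = \binom{\beta}{k-1}(\beta-k+1)/k}. The recurrence
#' is algebraically identical to the Gamma-function form and makes integer
#' orders exact: once \eqn{\beta - k + 1 = 0} every later weight is exactly 0
#' (the Gamma pole in the denominator).
#'
#' @param beta fractional order, > 0.
#' @param K truncation length, >= 1.
#' @return numeric vector of length K; `w[1] == 1`, `w[2] == -beta`.
#' @examples
#' glCoefficients(1.5, 3) # 1 -1.5 0.375
#' @export
glCoefficients <- function(beta, K) {
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  w <- numeric(K)
  w[1] <- 1
  if (K > 1L) {
    binom <- 1
    for (k in seq_len(K - 1L)) {
      binom <- binom * (beta - k + 1) / k
      w[k + 1L] <- (-1)^k * binom
    }
  }
  w
}

## shift a matrix by k along one axis with the operator's boundary rule:
## rows: row i takes value from row i - k; cols analogous.
.shiftLag <- function(H, k, axis, boundary) {
  if (k == 0L) return(H)
  n <- if (axis == "rows") nrow(H) else ncol(H)
  idx <- seq_len(n) - k
  if (boundary == "replicate") {
    idx <- pmax(idx, 1L)
    if (axis == "rows") H[idx, , drop = FALSE] else H[, idx, drop = FALSE]
  } else {
    out <- matrix(0, nrow(H), ncol(H))
    keep <- idx >= 1L
    if (any(keep)) {
      if (axis == "rows") {
        out[keep, ] <- H[idx[keep], , drop = FALSE]
      } else {
        out[, keep] <- H[, idx[keep], drop = FALSE]
      }
    }
    out
  }
}

#' Discrete fractional-order difference of a matrix
#'
#' Applies the Grunwald-Letnikov difference
#' \eqn{(D^\beta H)_{ij} = \sum_{k=0}^{K-1} w_k H_{i-k,j}} along rows, or the
#' analogue over the column index. Out-of-range lags follow the operator's
#' boundary rule.
#'
#' @param H numeric matrix.
#' @param op a [FracDiffOperator-class].
#' @param axis `"rows"` (first grid direction, down the gene axis) or
#'   `"cols"`.
#' @return matrix of the same shape as `H`.
#' @export
fracDiff <- function(H, op, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  H <- as.matrix(H)
  out <- matrix(0, nrow(H), ncol(H))
  for (k in seq_len(op@K) - 1L) {
    w <- op@weights[k + 1L]
    if (w != 0) out <- out + w * .shiftLag(H, k, axis, op@boundary)
  }
  out
}

#' Adjoint of the discrete fractional difference
#'
#' The exact linear-algebraic adjoint of [fracDiff()] under the Frobenius
#' inner product, including the boundary rule: for the zero boundary the
#' adjoint of the lag-k shift is the lead-k shift; for the replicate boundary
#' the clamped first index additionally accumulates the first k + 1 entries.
#' The fractional divergence of a two-component field (p1, p2) is
#' `-(fracAdjoint(p1, op, "rows") + fracAdjoint(p2, op, "cols"))`, the
#' real-valued discrete-calculus counterpart of the fractional divergence.
#'
#' @inheritParams fracDiff
#' @param P matrix of the same shape as the grid the operator acts on.
#' @return matrix of the same shape as `P`, satisfying
#'   `sum(fracDiff(U, op, axis) * P) == sum(U * fracAdjoint(P, op, axis))`.
#' @export
fracAdjoint <- function(P, op, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  P <- as.matrix(P)
  out <- matrix(0, nrow(P), ncol(P))
  n <- if (axis == "rows") nrow(P) else ncol(P)
  for (k in seq_len(op@K) - 1L) {
    w <- op@weights[k + 1L]
    if (w == 0) next
    ## adjoint of the lag-k shift: entry i collects p_{i+k}
    term <- matrix(0, nrow(P), ncol(P))
    src <- seq_len(n) + k
    keep <- src <= n
    if (any(keep)) {
      if (axis == "rows") {
        term[keep, ] <- P[src[keep], , drop = FALSE]
      } else {
        term[, keep] <- P[, src[keep], drop = FALSE]
      }
    }
    if (op@boundary == "replicate" && k > 0L) {
      ## clamped indices: rows 1..min(k+1, n) of P all mapped from index 1
      m <- min(k + 1L, n)
      if (axis == "rows") {
        term[1, ] <- colSums(P[seq_len(m), , drop = FALSE])
      } else {
        term[, 1] <- rowSums(P[, seq_len(m), drop = FALSE])
      }
    }
    out <- out + w * term
  }
  out
}

#' Anisotropic fractional total-variation energy
#'
#' \eqn{\sum_{ij} |D_1^\beta H_{ij}| + |D_2^\beta H_{ij}|}, the discrete
#' fractional TV seminorm (1-homogeneous in H).
#'
#' @inheritParams fracDiff
#' @return a single nonnegative number.
#' @export
aftvEnergy <- function(H, op) {
  sum(abs(fracDiff(H, op, "rows"))) + sum(abs(fracDiff(H, op, "cols")))
}

## separable Gaussian smoothing with replicate padding; sigma in grid units,
## kernel truncated at 3 sigma. sigma = 0 is the identity.
.gaussianSmooth <- function(H, sigma) {
  if (sigma <= 0) return(H)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  smooth1 <- function(M, axis) {
    out <- matrix(0, nrow(M), ncol(M))
    n <- if (axis == "rows") nrow(M) else ncol(M)
    for (j in seq_along(x)) {
      idx <- pmin(pmax(seq_len(n) + x[j], 1L), n)
      out <- out + kern[j] *
        (if (axis == "rows") M[idx, , drop = FALSE] else M[, idx, drop = FALSE])
    }
    out
  }
  smooth1(smooth1(H, "rows"), "cols")
}

#' Adaptive diffusion exponent field
#'
#' Computes the spatially varying exponent l(x,y) in (1, 2) that steers the
#' regulariser between Tikhonov-like smoothing (l near 2, flat regions) and
#' TV-like edge preservation (l near 1, sharp transitions). The gradient
#' magnitude g of the Gaussian-smoothed grid (first-order backward
#' differences, replicate boundary) is mapped through
#' `l = 1 + 1 / (1 + (g / kappa)^2)` and clamped to
#' `[1 + delta, 2 - delta]`.
#'
#' @param H numeric matrix (the grid being regularised).
#' @param kappa positive contrast scale; `NA` uses the median of the nonzero
#'   smoothed gradient magnitudes (1 if all are zero).
#' @param sigma Gaussian smoothing width, >= 0.
#' @param delta clamp margin in (0, 0.5).
#' @return matrix of exponents, same shape as `H`, all entries strictly
#'   inside (1, 2).
#' @export
adaptiveExponent <- function(H, kappa = NA_real_, sigma = 1, delta = 1e-3) {
  stopifnot(sigma >= 0, delta > 0, delta < 0.5)
  H <- as.matrix(H)
  d1 <- fracDiffOperator(1, 2, "replicate")
  Hs <- .gaussianSmooth(H, sigma)
  g <- sqrt(fracDiff(Hs, d1, "rows")^2 + fracDiff(Hs, d1, "cols")^2)
  if (is.na(kappa)) {
    nz <- g[g > 0]
    kappa <- if (length(nz)) median(nz) else 1
  }
  if (kappa <= 0) stop("kappa must be positive")
  l <- 1 + 1 / (1 + (g / kappa)^2)
  pmin(pmax(l, 1 + delta), 2 - delta)
}

## resolve the exponent field and absolute eps for a given grid
.aftvField <- function(H, params) {
  L <- params@exponentField
  if (!length(L)) {
    L <- adaptiveExponent(H, params@kappa, params@sigma, params@delta)
  } else if (!identical(dim(L), dim(H))) {
    stop("fixed exponent field shape does not match the grid")
  }
  list(L = L, eps = params@epsRel * (max(abs(H)) + 1))
}

#' Smoothed AFTV energy
#'
#' The differentiable surrogate
#' \eqn{\sum_{ij} ((D_1^\beta H)^2 + (D_2^\beta H)^2 + eps^2)^{l/2} / l}
#' whose exact gradient (for a frozen exponent field l) is returned by
#' [aftvGradient()]. Exposed mainly for gradient verification.
#'
#' @inheritParams aftvGradient
#' @return a single nonnegative number.
#' @export
aftvSmoothedEnergy <- function(H, params) {
  H <- as.matrix(H)
  fe <- .aftvField(H, params)
  op <- params@operator
  d1 <- fracDiff(H, op, "rows")
  d2 <- fracDiff(H, op, "cols")
  sum(((d1^2 + d2^2 + fe$eps^2)^(fe$L / 2)) / fe$L)
}

#' Gradient of the smoothed AFTV regulariser
#'
#' For a frozen exponent field l this is the exact gradient of
#' [aftvSmoothedEnergy()]:
#' \deqn{G = D_1^{\beta*}(D_1^\beta H \cdot W) + D_2^{\beta*}(D_2^\beta H \cdot W),
#'   \quad W = ((D_1^\beta H)^2 + (D_2^\beta H)^2 + eps^2)^{(l-2)/2},}
#' the discrete counterpart of the adaptive diffusion flow: the adjoint
#' operators applied to the fractional gradient rescaled by the magnitude
#' raised to l - 2. Flat regions (small magnitude, l near 2) diffuse almost
#' linearly; sharp transitions (l near 1) are preserved.
#'
#' @param H numeric matrix.
#' @param params an [AFTVParams-class]; a fixed `exponentField` freezes l,
#'   otherwise l is recomputed from `H` via [adaptiveExponent()].
#' @return matrix of the same shape as `H`.
#' @export
aftvGradient <- function(H, params) {
  H <- as.matrix(H)
  fe <- .aftvField(H, params)
  op <- params@operator
  d1 <- fracDiff(H, op, "rows")
  d2 <- fracDiff(H, op, "cols")
  W <- (d1^2 + d2^2 + fe$eps^2)^((fe$L - 2) / 2)
  G <- fracAdjoint(d1 * W, op, "rows") + fracAdjoint(d2 * W, op, "cols")
  if (any(!is.finite(G))) {
    stop("non-finite AFTV gradient; increase epsRel")
  }
  G
}
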