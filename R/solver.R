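#' Singular value thresholding
#'
#' The proximal operator of the nuclear norm: soft-thresholds the singular
#' values of M by `tau` (subtract and floor at zero) and reassembles,
#' minimising `tau * ||Q||_* + 0.5 * ||Q - M||_F^2`.
#'
#' @param M numeric matrix.
#' @param tau nonnegative threshold.
#' @return matrix of the same shape as `M`.
#' @examples
#' svt(diag(c(5, 2, 0.5)), 1) # diag(4, 1, 0)
#' @export
svt <- function(M, tau) {
  stopifnot(tau >= 0)
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop("non-finite input to svt")
  s <- svd(M)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$u[, keep, drop = FALSE] %*%
    (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Build the symmetrised similarity matrix
#'
#' `S = (R + t(R)) / 2`; symmetric by construction, nonnegative when R is.
#'
#' @param R square coefficient matrix.
#' @return symmetric matrix of the same shape.
#' @export
buildSimilarity <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("R must be square")
  (R + t(R)) / 2
}

#' AFTV-LRR objective value
#'
#' `0.5 * ||X - X R||_F^2 + alpha * ||R||_* + lambdaTV * AFTV(X R)` where
#' the AFTV term is the anisotropic fractional TV energy of the
#' reconstruction (see [aftvEnergy()]).
#'
#' @param X m x n preprocessed expression matrix.
#' @param R n x n coefficient matrix.
#' @param params a [SolverParams-class].
#' @return a single number.
#' @export
aftvObjective <- function(X, R, params) {
  fit <- X - X %*% R
  obj <- 0.5 * sum(fit^2) + params@alpha * sum(svd(R)$d)
  if (params@aftv@lambdaTV > 0) {
    obj <- obj + params@aftv@lambdaTV * aftvEnergy(X %*% R, params@aftv@operator)
  }
  obj
}

## apply the frozen-diffusivity AFTV operator T_W(H) = D1*(W . D1 H) +
## D2*(W . D2 H); SPD for W > 0 because the adjoints are exact
.aftvDiffuse <- function(H, W, op) {
  fracAdjoint(W * fracDiff(H, op, "rows"), op, "rows") +
    fracAdjoint(W * fracDiff(H, op, "cols"), op, "cols")
}

## One R update. Stationarity of the augmented Lagrangian
## L = f(R) + g(Q) + Y'(R - Q) + 1/(2 mu)||R - Q||_F^2 with the AFTV term
## treated by lagged diffusivity: the diffusivity weights
## W = (|D^b XR|^2 + eps^2)^{(l-2)/2} and the exponent field l are frozen at
## the previous reconstruction X R^l while D^b X R stays implicit, giving
## the SPD linear system
##   (X'X + (1/mu) I) R + lambdaTV X' T_W(X R) = X'X - Y + (1/mu) Q.
## Solved by preconditioned conjugate gradients (warm-started at R^l) with
## the cached Cholesky of X'X + (1/mu) I as preconditioner; for
## lambdaTV = 0 the cached factor solves the system in one shot. The result
## is projected onto the nonnegative orthant.
.updateR <- function(X, R, Q, Y, params, chXtX, XtX,
                     cgMaxIter = 40L, cgTol = 1e-9) {
  b <- XtX - Y + Q / params@mu
  lam <- params@aftv@lambdaTV
  psolve <- function(Z) backsolve(chXtX, backsolve(chXtX, Z, transpose = TRUE))
  if (lam == 0) {
    Rn <- psolve(b)
  } else {
    H <- X %*% R
    fe <- .aftvField(H, params@aftv)
    op <- params@aftv@operator
    d1 <- fracDiff(H, op, "rows")
    d2 <- fracDiff(H, op, "cols")
    W <- (d1^2 + d2^2 + fe$eps^2)^((fe$L - 2) / 2)
    if (any(!is.finite(W))) stop("non-finite AFTV diffusivity; increase epsRel")
    Aop <- function(Z) {
      XtX %*% Z + Z / params@mu +
        lam * crossprod(X, .aftvDiffuse(X %*% Z, W, op))
    }
    Rn <- R
    r <- b - Aop(Rn)
    z <- psolve(r)
    p <- z
    rz <- sum(r * z)
    nb <- sqrt(sum(b^2))
    for (it in seq_len(cgMaxIter)) {
      Ap <- Aop(p)
      a <- rz / sum(p * Ap)
      Rn <- Rn + a * p
      r <- r - a * Ap
      if (sqrt(sum(r^2)) < cgTol * nb) break
      z <- psolve(r)
      rz2 <- sum(r * z)
      p <- z + (rz2 / rz) * p
      rz <- rz2
    }
  }
  Rn[Rn < 0] <- 0
  Rn
}

## Q update: SVT of (R + mu Y) at threshold alpha*mu (the proximal scaling of
## alpha||Q||_* + 1/(2 mu)||Q - R - mu Y||_F^2), then optional nonnegative
## projection as in the published algorithm.
.updateQ <- function(R, Y, params) {
  Qn <- svt(R + params@mu * Y, params@alpha * params@mu)
  if (params@projectQ) Qn[Qn < 0] <- 0
  Qn
}

#' Fit the AFTV-LRR model by ADMM
#'
#' Learns a nonnegative low-rank cell-cell coefficient matrix R for the
#' preprocessed genes x cells matrix X by alternating:
#' an R update solving the SPD stationarity system of the augmented
#' Lagrangian — the adaptive fractional-TV term handled by lagged
#' diffusivity (diffusivity weights and exponent field frozen at the
#' previous reconstruction, the fractional differences of XR implicit),
#' solved by conjugate gradients preconditioned with the cached Cholesky
#' factor — a Q update by singular value thresholding with nonnegative
#' projection, and the multiplier step
#' `Y <- Y + (R - Q)/mu`. All three matrices start at zero. Iteration stops
#' when the successive change `||R_{l+1} - R_l||_F` (divided by
#' `1 + ||R_l||_F` in the default relative mode) falls below `tol`, or at
#' `maxIter`. The adaptive exponent field is recomputed once per iteration
#' from the current reconstruction; the Cholesky factor of
#' `X'X + (1/mu) I` is computed once and reused.
#'
#' @param X preprocessed genes x cells matrix (or SummarizedExperiment,
#'   first assay), finite values.
#' @param params a [SolverParams-class]; built from `...` when missing.
#' @param ... forwarded to [solverParams()] when `params` is NULL.
#' @return an [AFTVFit-class] with the final state, the similarity matrix
#'   `S = (R + t(R))/2` and the convergence trace.
#' @examples
#' sce <- standardFixture()
#' X <- preprocessCells(SummarizedExperiment::assay(sce))
#' fit <- fitAFTVLRR(X, maxIter = 30)
#' fit
#' @export
fitAFTVLRR <- function(X, params = NULL, ...) {
  if (is(X, "SummarizedExperiment")) X <- SummarizedExperiment::assay(X, 1)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite")
  if (is.null(params)) params <- solverParams(...)
  n <- ncol(X)
  XtX <- crossprod(X)
  chXtX <- chol(XtX + diag(n) / params@mu)
  R <- Q <- Y <- matrix(0, n, n)
  tr <- vector("list", params@maxIter)
  converged <- FALSE
  iter <- 0L
  for (l in seq_len(params@maxIter)) {
    Rn <- .updateR(X, R, Q, Y, params, chXtX, XtX)
    Qn <- .updateQ(Rn, Y, params)
    Y <- Y + (Rn - Qn) / params@mu
    change <- sqrt(sum((Rn - R)^2))
    dual <- sqrt(sum((Qn - Q)^2)) / params@mu
    primal <- sqrt(sum((Rn - Qn)^2))
    obj <- aftvObjective(X, Rn, params)
    if (!is.finite(obj)) {
      warning("objective became non-finite at iteration ", l,
              "; returning the last finite iterate. ",
              "Consider a larger mu or smaller lambdaTV.")
      break
    }
    relChange <- if (params@relativeTol) {
      change / (1 + sqrt(sum(R^2)))
    } else {
      change
    }
    R <- Rn
    Q <- Qn
    iter <- l
    tr[[l]] <- c(iteration = l, objective = obj, primal_residual = primal,
                 dual_residual = dual, change = change)
    if (relChange < params@tol) {
      converged <- TRUE
      break
    }
  }
  trace <- as.data.frame(do.call(rbind, tr[seq_len(iter)]))
  dimnames(R) <- dimnames(Q) <- dimnames(Y) <-
    list(colnames(X), colnames(X))
  if (!converged && iter == params@maxIter) {
    message("fitAFTVLRR: maximum iterations (", params@maxIter,
            ") reached before tolerance")
  }
  new("AFTVFit",
    R = R, Q = Q, Y = Y, S = buildSimilarity(R), trace = trace,
    converged = converged, iterations = iter, params = params
  )
}

#' Export a convergence trace to CSV
#'
#' Writes the per-iteration objective, primal and dual residuals and
#' successive change of a fit, for convergence-diagnostic plots.
#'
#' @param fit an [AFTVFit-class].
#' @param path output CSV path.
#' @export
writeConvergenceTrace <- function(fit, path) {
  utils::write.csv(convergenceTrace(fit), path, row.names = FALSE)
  invisible(path)
}
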