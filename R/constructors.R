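#' Create a fractional difference operator
#'
#' Builds the discrete Grunwald-Letnikov operator of order `beta` with
#' truncation length `K`; the weights are computed by [glCoefficients()].
#'
#' @param beta fractional order in (0, 2]; `beta = 1` recovers the classical
#'   backward first difference (for K >= 2).
#' @param K truncation length; values of 3 or more are recommended for stable
#'   behaviour on expression grids.
#' @param boundary `"replicate"` (default) clamps out-of-range indices to the
#'   grid edge, so integer orders annihilate constants; `"zero"` treats
#'   out-of-range values as 0.
#' @return a [FracDiffOperator-class].
#' @examples
#' fracDiffOperator(1.5, 3)
#' @export
fracDiffOperator <- function(beta = 1.3, K = 3, boundary = c("replicate", "zero")) {
  boundary <- match.arg(boundary)
  new("FracDiffOperator",
    beta = as.numeric(beta), K = as.integer(K),
    weights = glCoefficients(beta, K), boundary = boundary
  )
}

#' Create AFTV regulariser parameters
#'
#' @param beta,K,boundary passed to [fracDiffOperator()]; ignored when
#'   `operator` is supplied.
#' @param operator an explicit [FracDiffOperator-class], overriding
#'   `beta`/`K`/`boundary`.
#' @param lambdaTV nonnegative weight on the AFTV term (default 0.02; 0
#'   gives the plain nonnegative LRR baseline). On L2-normalised matrices
#'   the fractional TV of XR, summed over the whole genes x cells grid, is
#'   orders of magnitude larger than the Frobenius fidelity, so the default
#'   keeps the regulariser at a corrective, denoising scale rather than
#'   letting it dominate and flatten the reconstruction.
#' @param epsRel relative gradient stabiliser (default 1e-8; the absolute eps
#'   is `epsRel * (max|H| + 1)` for the grid H at hand).
#' @param kappa contrast scale of the adaptive exponent; `NA` (default) means
#'   the median nonzero smoothed gradient magnitude, per call.
#' @param sigma Gaussian smoothing width in grid units for the exponent's
#'   gradient estimate (default 1).
#' @param delta clamp margin keeping the exponent in [1 + delta, 2 - delta].
#' @param exponentField optional fixed exponent matrix (advanced; used to
#'   freeze l(x,y) instead of recomputing it adaptively).
#' @return an [AFTVParams-class].
#' @export
aftvParams <- function(beta = 1.3, K = 3, boundary = "replicate",
                       operator = NULL, lambdaTV = 0.02, epsRel = 1e-8,
                       kappa = NA_real_, sigma = 1, delta = 1e-3,
                       exponentField = NULL) {
  if (is.null(operator)) operator <- fracDiffOperator(beta, K, boundary)
  new("AFTVParams",
    operator = operator, lambdaTV = as.numeric(lambdaTV),
    epsRel = as.numeric(epsRel), kappa = as.numeric(kappa),
    sigma = as.numeric(sigma), delta = as.numeric(delta),
    exponentField = if (is.null(exponentField)) {
      matrix(numeric(0), 0, 0)
    } else {
      as.matrix(exponentField)
    }
  )
}

#' Create ADMM solver parameters
#'
#' The defaults are the package's reference configuration: `alpha = 0.5`,
#' `mu = 0.25`, fractional order 1.3 with truncation 3, AFTV weight 0.02.
#'
#' @param alpha positive nuclear-norm weight.
#' @param mu positive penalty parameter (1/mu convention: dual step and
#'   quadratic penalty are scaled by 1/mu, so smaller mu couples R and Q
#'   more tightly).
#' @param aftv an [AFTVParams-class]; built from `...` if missing.
#' @param tol stopping tolerance on the successive change of R
#'   (default 1e-5, relative).
#' @param relativeTol divide the change by (1 + ||R||_F) before the test.
#' @param maxIter iteration cap (default 100).
#' @param projectQ apply the nonnegative projection to Q after singular value
#'   thresholding (default TRUE, the algorithm as published; FALSE keeps the
#'   exact nuclear-norm proximal step).
#' @param seed integer recorded for reproducibility.
#' @param ... forwarded to [aftvParams()] when `aftv` is not given
#'   (e.g. `beta`, `K`, `lambdaTV`).
#' @return a [SolverParams-class].
#' @examples
#' solverParams(alpha = 0.5, mu = 1, beta = 1.3, K = 3)
#' @export
solverParams <- function(alpha = 0.5, mu = 0.25, aftv = NULL, tol = 1e-5,
                         relativeTol = TRUE, maxIter = 100L, projectQ = TRUE,
                         seed = 1L, ...) {
  if (is.null(aftv)) aftv <- aftvParams(...)
  new("SolverParams",
    alpha = as.numeric(alpha), mu = as.numeric(mu), aftv = aftv,
    tol = as.numeric(tol), relativeTol = isTRUE(relativeTol),
    maxIter = as.integer(maxIter), projectQ = isTRUE(projectQ),
    seed = as.integer(seed)
  )
}

#' @describeIn AFTVFit-class the learnt n x n coefficient matrix R.
#' @param object an `AFTVFit` or `SpectralClustering` object.
#' @export
coefMatrix <- function(object) {
  stopifnot(is(object, "AFTVFit"))
  object@R
}

#' @describeIn AFTVFit-class the symmetrised similarity matrix S = (R + t(R))/2.
#' @export
similarityMatrix <- function(object) {
  stopifnot(is(object, "AFTVFit"))
  object@S
}

#' @describeIn AFTVFit-class per-iteration convergence trace as a data.frame.
#' @export
convergenceTrace <- function(object) {
  stopifnot(is(object, "AFTVFit"))
  object@trace
}

#' @describeIn AFTVFit-class whether the stopping rule fired before `maxIter`.
#' @export
isConverged <- function(object) {
  stopifnot(is(object, "AFTVFit"))
  object@converged
}

#' @describeIn SpectralClustering-class integer cluster labels (1..k) per cell.
#' @param object a `SpectralClustering` object.
#' @export
clusterLabels <- function(object) {
  stopifnot(is(object, "SpectralClustering"))
  object@labels
}

#' @describeIn SpectralClustering-class the smallest k + 1 Laplacian
#'   eigenvalues (eigengap report).
#' @export
laplacianEigenvalues <- function(object) {
  stopifnot(is(object, "SpectralClustering"))
  object@eigenvalues
}
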