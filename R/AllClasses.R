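#' @import methods
#' @importFrom stats rnorm runif rbinom rpois median sd kmeans setNames
#' @importFrom utils read.csv write.csv read.table write.table
NULL

#' Discrete Grunwald-Letnikov fractional difference operator
#'
#' Holds the fractional order \eqn{\beta}, the truncation length K and the
#' precomputed signed generalised-binomial weights
#' \eqn{w_k = (-1)^k \binom{\beta}{k}}, together with the boundary rule used
#' when the lagged index runs off the grid.
#'
#' @slot beta fractional order, in (0, 2].
#' @slot K integer truncation length (number of lagged grid points).
#' @slot weights numeric vector of length K; `weights[1] == 1` and
#'   `weights[2] == -beta` exactly.
#' @slot boundary `"replicate"` (clamp to the first index) or `"zero"`
#'   (out-of-range values contribute nothing).
#'
#' @seealso [fracDiffOperator()], [fracDiff()], [fracAdjoint()]
#' @export
setClass("FracDiffOperator",
  representation(
    beta = "numeric",
    K = "integer",
    weights = "numeric",
    boundary = "character"
  )
)

setValidity("FracDiffOperator", function(object) {
  msg <- character()
  if (length(object@beta) != 1 || !is.finite(object@beta) || object@beta <= 0)
    msg <- c(msg, "beta must be a single positive finite number")
  if (length(object@K) != 1 || object@K < 1L)
    msg <- c(msg, "K must be a positive integer")
  if (length(object@weights) != object@K || any(!is.finite(object@weights)))
    msg <- c(msg, "weights must be finite and of length K")
  if (length(object@weights) >= 1 && object@weights[1] != 1)
    msg <- c(msg, "weights[1] must be exactly 1")
  if (length(object@weights) >= 2 && object@weights[2] != -object@beta)
    msg <- c(msg, "weights[2] must be exactly -beta")
  if (!object@boundary %in% c("replicate", "zero"))
    msg <- c(msg, "boundary must be 'replicate' or 'zero'")
  if (length(msg)) msg else TRUE
})

#' Parameters of the adaptive fractional total-variation regulariser
#'
#' Bundles the fractional difference operator with the adaptive-exponent
#' policy and the smoothing stabiliser used inside the regulariser gradient.
#' The spatially varying exponent l(x,y) in (1,2) is recomputed from the
#' current reconstruction at each outer solver iteration unless a fixed field
#' is supplied.
#'
#' @slot operator a [FracDiffOperator-class].
#' @slot lambdaTV nonnegative weight on the AFTV term; 0 turns the regulariser
#'   off (plain nonnegative low-rank representation).
#' @slot epsRel relative stabiliser; the absolute eps used for a grid H is
#'   `epsRel * (max(abs(H)) + 1)`, keeping the smoothing scale-invariant.
#' @slot kappa contrast scale of the exponent map; `NA` means "median of the
#'   nonzero smoothed gradient magnitudes", recomputed per call.
#' @slot sigma Gaussian pre-smoothing width (grid units) for the gradient
#'   magnitude feeding the exponent map.
#' @slot delta clamp margin: l is kept in [1 + delta, 2 - delta].
#' @slot exponentField optional fixed exponent matrix; 0x0 means adaptive.
#'
#' @seealso [aftvParams()], [aftvGradient()], [adaptiveExponent()]
#' @export
setClass("AFTVParams",
  representation(
    operator = "FracDiffOperator",
    lambdaTV = "numeric",
    epsRel = "numeric",
    kappa = "numeric",
    sigma = "numeric",
    delta = "numeric",
    exponentField = "matrix"
  )
)

setValidity("AFTVParams", function(object) {
  msg <- character()
  if (object@lambdaTV < 0) msg <- c(msg, "lambdaTV must be >= 0")
  if (object@epsRel <= 0) msg <- c(msg, "epsRel must be > 0")
  if (!is.na(object@kappa) && object@kappa <= 0)
    msg <- c(msg, "kappa must be positive (or NA for automatic)")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@delta <= 0 || object@delta >= 0.5)
    msg <- c(msg, "delta must lie in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' ADMM solver parameters
#'
#' @slot alpha positive nuclear-norm weight controlling low-rankness.
#' @slot mu positive penalty parameter; the dual step and quadratic penalty
#'   are scaled by 1/mu (large mu = weak penalty), matching the update
#'   Y <- Y + (R - Q)/mu.
#' @slot aftv an [AFTVParams-class].
#' @slot tol stopping tolerance on the successive change of R.
#' @slot relativeTol if TRUE (default) the change is divided by
#'   (1 + ||R||_F) before comparison with `tol`.
#' @slot maxIter iteration cap.
#' @slot projectQ project Q onto the nonnegative orthant after singular value
#'   thresholding (algorithm default); disable to keep the exact nuclear-norm
#'   proximal step.
#' @slot seed integer kept for the reproducibility contract (the solver itself
#'   is deterministic from the zero initialisation).
#'
#' @seealso [solverParams()], [fitAFTVLRR()]
#' @export
setClass("SolverParams",
  representation(
    alpha = "numeric",
    mu = "numeric",
    aftv = "AFTVParams",
    tol = "numeric",
    relativeTol = "logical",
    maxIter = "integer",
    projectQ = "logical",
    seed = "integer"
  )
)

setValidity("SolverParams", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
  if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Fitted AFTV-LRR model
#'
#' Result of [fitAFTVLRR()]: the final ADMM state (coefficient matrix R,
#' auxiliary Q, multiplier Y), the symmetrised similarity matrix
#' S = (R + t(R))/2, per-iteration convergence traces and a convergence flag.
#'
#' @slot R,Q,Y n x n matrices of the final ADMM state; R and Q are
#'   entrywise nonnegative.
#' @slot S symmetrised nonnegative similarity matrix.
#' @slot trace data.frame with columns `iteration`, `objective`,
#'   `primal_residual` (||R - Q||_F), `dual_residual`
#'   (||Q_{l+1} - Q_l||_F / mu) and `change` (||R_{l+1} - R_l||_F).
#' @slot converged TRUE if the stopping rule fired before `maxIter`.
#' @slot iterations number of iterations performed.
#' @slot params the [SolverParams-class] used.
#'
#' @seealso [coefMatrix()], [similarityMatrix()], [convergenceTrace()]
#' @export
setClass("AFTVFit",
  representation(
    R = "matrix",
    Q = "matrix",
    Y = "matrix",
    S = "matrix",
    trace = "data.frame",
    converged = "logical",
    iterations = "integer",
    params = "SolverParams"
  )
)

setValidity("AFTVFit", function(object) {
  msg <- character()
  n <- ncol(object@R)
  if (nrow(object@R) != n) msg <- c(msg, "R must be square")
  for (nm in c("Q", "Y", "S"))
    if (!identical(dim(slot(object, nm)), c(n, n)))
      msg <- c(msg, paste(nm, "must match the shape of R"))
  if (min(object@R) < 0) msg <- c(msg, "R must be entrywise nonnegative")
  if (min(object@Q) < 0) msg <- c(msg, "Q must be entrywise nonnegative")
  if (length(msg)) msg else TRUE
})

#' Spectral clustering result
#'
#' @slot labels integer cluster label per cell, values in 1..k.
#' @slot k number of clusters requested.
#' @slot seed RNG seed used for the k-means restarts.
#' @slot eigenvalues the smallest k + 1 eigenvalues of the symmetric
#'   normalised Laplacian, for eigengap inspection.
#'
#' @seealso [spectralClustering()], [clusterLabels()]
#' @export
setClass("SpectralClustering",
  representation(
    labels = "integer",
    k = "integer",
    seed = "integer",
    eigenvalues = "numeric"
  )
)

setValidity("SpectralClustering", function(object) {
  msg <- character()
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(unique(object@labels)) > object@k)
    msg <- c(msg, "more distinct labels than k")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FracDiffOperator", function(object) {
  cat(sprintf(
    "FracDiffOperator: beta = %g, K = %d, boundary = %s\n  weights: %s\n",
    object@beta, object@K, object@boundary,
    paste(signif(object@weights, 6), collapse = " ")
  ))
})

setMethod("show", "AFTVParams", function(object) {
  cat(sprintf(
    "AFTVParams: lambdaTV = %g, beta = %g, K = %d, sigma = %g, delta = %g, kappa = %s\n",
    object@lambdaTV, object@operator@beta, object@operator@K,
    object@sigma, object@delta,
    if (is.na(object@kappa)) "auto (median gradient)" else format(object@kappa)
  ))
})

setMethod("show", "SolverParams", function(object) {
  cat(sprintf(
    "SolverParams: alpha = %g, mu = %g, tol = %g (%s), maxIter = %d\n",
    object@alpha, object@mu, object@tol,
    if (object@relativeTol) "relative" else "absolute", object@maxIter
  ))
  show(object@aftv)
})

setMethod("show", "AFTVFit", function(object) {
  n <- ncol(object@R)
  tr <- object@trace
  cat(sprintf(
    "AFTVFit on %d cells: %d iterations (%s)\n", n, object@iterations,
    if (object@converged) "converged" else "max iterations reached"
  ))
  if (nrow(tr)) {
    last <- tr[nrow(tr), ]
    cat(sprintf(
      "  objective %.6g | primal %.3g | dual %.3g | change %.3g\n",
      last$objective, last$primal_residual, last$dual_residual, last$change
    ))
  }
})

setMethod("show", "SpectralClustering", function(object) {
  cat(sprintf(
    "SpectralClustering: %d cells in %d clusters (sizes: %s)\n",
    length(object@labels), object@k,
    paste(tabulate(object@labels, object@k), collapse = ", ")
  ))
})
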