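#' Run the full clustering pipeline
#'
#' Wires preprocessing, AFTV-LRR fitting, spectral clustering and (when
#' ground truth is available) evaluation and marker ranking, writing every
#' intermediate artifact to `outDir`:
#' `preprocessed.csv`, `similarity.csv`, `trace.csv`, `labels.txt`,
#' `params.txt`, plus `metrics.txt` when truth labels are given and
#' `markers.tsv` when `topMarkers` is set. Identical inputs and seed give
#' identical outputs.
#'
#' @param input a genes x cells matrix, a SummarizedExperiment, or a file
#'   path readable by [readExpressionMatrix()].
#' @param k number of clusters.
#' @param truthLabels optional reference labels: a vector or a path to a
#'   one-label-per-line file.
#' @param outDir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param format,transpose passed to [readExpressionMatrix()] for file input.
#' @param threshold,scaleFactor preprocessing parameters
#'   (see [preprocessCells()]).
#' @param alpha,mu,beta,K,lambdaTV,tol,maxIter solver hyperparameters
#'   (see [solverParams()]).
#' @param seed seed for the clustering restarts.
#' @param topMarkers if not `NULL`, rank this many marker genes per predicted
#'   cluster on the preprocessed matrix.
#' @param verbose print stage progress.
#' @return invisibly, a list with elements `X` (preprocessed matrix), `fit`
#'   ([AFTVFit-class]), `clustering` ([SpectralClustering-class]), `labels`,
#'   `metrics` (or NULL) and `markers` (or NULL).
#' @export
runPipeline <- function(input, k, truthLabels = NULL, outDir = NULL,
                        format = "auto", transpose = FALSE,
                        threshold = 0.95, scaleFactor = 1e5,
                        alpha = 0.5, mu = 0.25, beta = 1.3, K = 3,
                        lambdaTV = 0.02, tol = 1e-5, maxIter = 100L,
                        seed = 1L, topMarkers = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[scAFTV] ", ...)
  X <- if (is.character(input)) {
    say("reading ", input)
    readExpressionMatrix(input, format, transpose)
  } else if (is(input, "SummarizedExperiment")) {
    SummarizedExperiment::assay(input, 1)
  } else {
    as.matrix(input)
  }
  if (is.character(truthLabels) && length(truthLabels) == 1 &&
      file.exists(truthLabels)) {
    truthLabels <- readLabels(truthLabels)
  }
  if (!is.null(truthLabels) && length(truthLabels) != ncol(X)) {
    stop("preprocess stage: truth labels (", length(truthLabels),
         ") do not match the cell count (", ncol(X), ")")
  }

  say("preprocessing (filter > ", threshold, " zeros, normalise, L2)")
  Xp <- tryCatch(
    preprocessCells(X, threshold = threshold, scaleFactor = scaleFactor),
    error = function(e) stop("preprocess stage: ", conditionMessage(e))
  )

  params <- solverParams(alpha = alpha, mu = mu, tol = tol,
                         maxIter = maxIter, seed = seed,
                         beta = beta, K = K, lambdaTV = lambdaTV)
  say("fitting AFTV-LRR (alpha=", alpha, ", mu=", mu, ", beta=", beta,
      ", K=", K, ", lambdaTV=", lambdaTV, ")")
  fit <- tryCatch(
    fitAFTVLRR(Xp, params),
    error = function(e) stop("solver stage: ", conditionMessage(e))
  )
  if (!isConverged(fit)) {
    say("solver hit maxIter = ", maxIter, " before tolerance")
  }

  say("spectral clustering into k = ", k)
  cl <- tryCatch(
    spectralClustering(similarityMatrix(fit), k, seed = seed),
    error = function(e) stop("clustering stage: ", conditionMessage(e))
  )
  labels <- clusterLabels(cl)

  metrics <- NULL
  if (!is.null(truthLabels)) {
    metrics <- clusterMetrics(truthLabels, labels)
    say(sprintf("ARI = %.4f, NMI = %.4f", metrics$ari, metrics$nmi))
  }
  markers <- NULL
  if (!is.null(topMarkers)) {
    say("ranking top ", topMarkers, " markers per cluster")
    markers <- rankMarkerGenes(Xp, labels, topN = topMarkers)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeExpressionMatrix(Xp, file.path(outDir, "preprocessed.csv"), "csv")
    utils::write.csv(similarityMatrix(fit),
                     file.path(outDir, "similarity.csv"))
    writeConvergenceTrace(fit, file.path(outDir, "trace.csv"))
    writeLabels(labels, file.path(outDir, "labels.txt"))
    writeLines(c(
      sprintf("alpha: %g", alpha), sprintf("mu: %g", mu),
      sprintf("beta: %g", beta), sprintf("K: %d", as.integer(K)),
      sprintf("lambdaTV: %g", lambdaTV), sprintf("tol: %g", tol),
      sprintf("maxIter: %d", as.integer(maxIter)),
      sprintf("seed: %d", as.integer(seed)),
      sprintf("threshold: %g", threshold),
      sprintf("scaleFactor: %g", scaleFactor),
      sprintf("k: %d", as.integer(k)),
      sprintf("iterations: %d", fit@iterations),
      sprintf("converged: %s", isConverged(fit))
    ), file.path(outDir, "params.txt"))
    if (!is.null(metrics)) {
      writeLines(c(
        sprintf("ari: %.10f", metrics$ari),
        sprintf("nmi: %.10f", metrics$nmi),
        sprintf("rand_index: %.10f", metrics$rand_index)
      ), file.path(outDir, "metrics.txt"))
    }
    if (!is.null(markers)) {
      writeMarkerTable(markers, file.path(outDir, "markers.tsv"))
    }
  }
  invisible(list(X = Xp, fit = fit, clustering = cl, labels = labels,
                 metrics = metrics, markers = markers))
}
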