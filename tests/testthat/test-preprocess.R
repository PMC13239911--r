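makeCsv <- function(M, sep = ",", ext = ".csv") {
  f <- tempfile(fileext = ext)
  utils::write.table(data.frame(gene = rownames(M), M, check.names = FALSE),
                     f, sep = sep, row.names = FALSE, quote = FALSE)
  f
}

test_that("dense CSV/TSV round-trips preserve values and identifiers", {
  M <- matrix(c(0, 1, 2, 3, 4, 0, 7, 8, 9, 1, 0, 2), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  f <- makeCsv(M)
  X <- readExpressionMatrix(f)
  expect_equal(X, M)
  f2 <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(M, f2, "tsv")
  expect_equal(readExpressionMatrix(f2), M)
  # transpose flag for cells x genes storage
  ft <- makeCsv(t(M))
  expect_equal(readExpressionMatrix(ft, transpose = TRUE), t(t(M)))
})

test_that("Matrix-Market round-trip keeps sparsity pattern and sidecar ids", {
  M <- matrix(0, 4, 3, dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  M[c(1, 5, 7, 10, 12)] <- c(2, 1, 3, 4, 5)
  d <- file.path(tempfile(), "mm")
  dir.create(d, recursive = TRUE)
  f <- file.path(d, "expr.mtx")
  writeExpressionMatrix(M, f, "mtx")
  X <- readExpressionMatrix(f)
  expect_equal(X, M)
  expect_identical(sum(X != 0), 5L)
  # without sidecars, identifiers are auto-generated
  file.remove(file.path(d, "genes.txt"), file.path(d, "barcodes.txt"))
  X2 <- readExpressionMatrix(f)
  expect_identical(rownames(X2), paste0("gene_", 1:4))
})

test_that("readers reject malformed input", {
  M <- matrix(c(1, -1, 2, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  f <- makeCsv(M)
  expect_error(readExpressionMatrix(f), "negative expression value")
  expect_error(readExpressionMatrix(tempfile()), "not found")
  # mismatched sidecar length
  d <- file.path(tempfile(), "mm")
  dir.create(d, recursive = TRUE)
  f2 <- file.path(d, "expr.mtx")
  writeExpressionMatrix(abs(M), f2, "mtx")
  writeLines(c("a", "b", "c"), file.path(d, "genes.txt"))
  expect_error(readExpressionMatrix(f2), "identifier file")
})

test_that("gene filtering removes exactly the genes above the zero-fraction cutoff", {
  set.seed(1)
  n <- 100
  X <- rbind(
    allzero = rep(0, n),
    mostly = c(rep(0, 96), 1:4),
    boundary = c(rep(0, 95), 1:5),
    dense = runif(n) + 0.5
  )
  colnames(X) <- paste0("c", seq_len(n))
  Y <- filterGenes(X, 0.95)
  expect_identical(rownames(Y), c("boundary", "dense")) # 95/100 kept: strict >
  expect_identical(attr(Y, "removed"), c("allzero", "mostly"))
  expect_identical(colnames(Y), colnames(X))
  # toy fractions {1.0, 0.96, 0.5} at 0.95: both 1.0 and 0.96 exceed the
  # cutoff, so exactly one gene survives
  X2 <- rbind(g1 = rep(0, 50), g2 = c(rep(0, 48), 1, 1),
              g3 = c(rep(0, 25), rep(1, 25)))
  colnames(X2) <- paste0("c", 1:50)
  X2f <- filterGenes(X2, 0.95)
  expect_identical(rownames(X2f), "g3")
  expect_identical(attr(X2f, "removed"), c("g1", "g2"))
  expect_error(filterGenes(X2, -0.1))
  expect_error(filterGenes(matrix(0, 2, 3), 0.5), "all genes filtered")
})

test_that("gene filtering is idempotent", {
  fx <- fixtureMatrix(seed = 5)
  X1 <- filterGenes(fx$X, 0.6)
  X2 <- filterGenes(X1, 0.6)
  expect_equal(unname(X2), unname(X1))
})

test_that("log transform applies log2(x + 1) entrywise", {
  X <- matrix(c(0, 1, 3, 7), 2, 2,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_equal(logTransform(X),
               matrix(c(0, 1, 2, 3), 2, 2,
                      dimnames = dimnames(X)))
  expect_error(logTransform(matrix(-1)), "nonnegative")
})

test_that("count normalisation matches the formula and is library-size invariant", {
  X <- matrix(c(1, 3, 0, 2), 2, 2,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  N <- normalizeCounts(X, 1e5)
  expect_equal(N["a", "c1"], log2(1 / 4 * 1e5 + 1))
  expect_equal(N["a", "c1"], 14.6096, tolerance = 1e-4)
  expect_equal(N["a", "c2"], 0) # zero stays zero
  # exact invariance to per-cell rescaling
  X2 <- X
  X2[, 1] <- X2[, 1] * 17.3
  expect_equal(normalizeCounts(X2, 1e5), N)
  # all-zero cell: left zero, warned
  X3 <- cbind(X, c0 = c(0, 0))
  expect_warning(N3 <- normalizeCounts(X3, 1e5), "all-zero")
  expect_equal(N3[, "c0"], c(a = 0, b = 0))
})

test_that("L2 normalisation yields unit columns and keeps zero columns", {
  X <- cbind(a = c(3, 4), b = c(0, 0), c = c(1, 0))
  Y <- l2NormalizeCells(X)
  expect_equal(Y[, "a"], c(0.6, 0.8))
  expect_equal(Y[, "b"], c(0, 0))
  nrm <- sqrt(colSums(Y^2))
  expect_equal(unname(nrm[c("a", "c")]), c(1, 1), tolerance = 1e-12)
})

test_that("the preprocessing pipeline preserves cell count and order", {
  fx <- fixtureMatrix()
  Xp <- preprocessCells(fx$X)
  expect_identical(colnames(Xp), colnames(fx$X))
  expect_lte(nrow(Xp), nrow(fx$X))
  expect_equal(unname(sqrt(colSums(Xp^2))), rep(1, ncol(Xp)), tolerance = 1e-12)
})

test_that("preprocessing methods work on SummarizedExperiment containers", {
  sce <- simulateCells(nClusters = 2, cellsPerCluster = 4, nGenes = 30,
                       seed = 2, dropoutRate = 0.6)
  out <- preprocessCells(sce)
  expect_s4_class(out, "SingleCellExperiment")
  expect_identical(colnames(out), colnames(sce))
  Xm <- preprocessCells(SummarizedExperiment::assay(sce, 1))
  expect_equal(unname(SummarizedExperiment::assay(out, 1)), unname(Xm))
  # ground-truth labels ride along with the container
  expect_identical(SummarizedExperiment::colData(out)$cluster,
                   SummarizedExperiment::colData(sce)$cluster)
})

test_that("label files round-trip", {
  f <- tempfile()
  writeLabels(c("T", "B", "NK"), f)
  expect_identical(readLabels(f), c("T", "B", "NK"))
  expect_error(readLabels(tempfile()), "not found")
})
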