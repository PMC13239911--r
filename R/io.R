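#' Read an expression matrix
#'
#' Reads a genes x cells nonnegative expression matrix from dense CSV/TSV
#' (first column gene identifiers, header row cell identifiers) or
#' Matrix-Market `.mtx` with sidecar identifier files `genes.txt` and
#' `barcodes.txt` next to the matrix (one identifier per line; auto-generated
#' `gene_i` / `cell_j` names are used when the sidecars are absent).
#'
#' @param path path to the matrix file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`; guessed from the file extension
#'   when missing.
#' @param transpose set TRUE for files stored cells x genes.
#' @return numeric matrix, genes in rows, cells in columns, with unique
#'   dimnames; negative values are rejected.
#' @importFrom Matrix readMM
#' @export
readExpressionMatrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                                 transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
      stop("cannot guess format from extension; pass format explicitly")
    )
  }
  if (format == "mtx") {
    M <- as.matrix(Matrix::readMM(path))
    side <- function(f, n, prefix) {
      p <- file.path(dirname(path), f)
      if (file.exists(p)) {
        ids <- readLines(p)
        if (length(ids) != n) {
          stop("identifier file ", f, " has ", length(ids),
               " entries but the matrix dimension is ", n)
        }
        ids
      } else {
        paste0(prefix, seq_len(n))
      }
    }
    rownames(M) <- side("genes.txt", nrow(M), "gene_")
    colnames(M) <- side("barcodes.txt", ncol(M), "cell_")
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            row.names = 1, check.names = FALSE)
    M <- as.matrix(df)
    storage.mode(M) <- "double"
  }
  if (transpose) M <- t(M)
  if (anyNA(M)) stop("matrix contains missing values")
  if (min(M) < 0) stop("negative expression value in ", path)
  if (anyDuplicated(rownames(M))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(M))) stop("duplicate cell identifiers")
  M
}

#' Write an expression matrix
#'
#' Inverse of [readExpressionMatrix()]: dense CSV/TSV with gene identifiers in
#' the first column, or Matrix-Market with `genes.txt` / `barcodes.txt`
#' sidecars.
#'
#' @param X genes x cells matrix with dimnames.
#' @param path output file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @importFrom Matrix writeMM Matrix
#' @export
writeExpressionMatrix <- function(X, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  X <- as.matrix(X)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), path)
    writeLines(rownames(X), file.path(dirname(path), "genes.txt"))
    writeLines(colnames(X), file.path(dirname(path), "barcodes.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    utils::write.table(
      data.frame(gene = rownames(X), X, check.names = FALSE),
      path, sep = sep, row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Read / write cell labels
#'
#' Plain text, one label per line, aligned to the cell (column) order of the
#' matrix they accompany.
#'
#' @param path file path.
#' @return character vector of labels.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  labs <- readLines(path)
  labs <- labs[nzchar(labs)]
  if (!length(labs)) stop("empty label file: ", path)
  labs
}

#' @rdname readLabels
#' @param labels vector of labels.
#' @export
writeLabels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}
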