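# Readers and writers for the dense-CSV / sparse-MTX exchange formats.
# Dense matrices: CSV with a header row of feature names and the first
# column holding sample names. Sparse matrices: Matrix Market triplets plus
# features.tsv / barcodes.tsv sidecars, assumed features x observations
# (the genomics convention) unless transpose = FALSE.

#' Read / write a dense data matrix as CSV
#'
#' Header row = feature names, first column = sample names; values numeric.
#'
#' @param path File path.
#' @param x Numeric matrix (observations x features) with dimnames.
#' @param digits Significant digits written.
#' @return `read_matrix_csv()`: numeric matrix with dimnames.
#'   `write_matrix_csv()`: `path`, invisibly.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("non-numeric values in '%s'", path), call. = FALSE)
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_matrix_csv
#' @export
write_matrix_csv <- function(x, path, digits = 15) {
  x <- as_num_matrix(x, "x")
  df <- data.frame(sample = rownames(x) %||% paste0("s", seq_len(nrow(x))),
                   signif(x, digits), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sparse Matrix Market count matrix with sidecar names
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` under `dir` (or a
#' file prefix). The MTX payload is assumed features x observations and is
#' transposed to the package's observations x features orientation unless
#' `transpose = FALSE`.
#'
#' @param dir Directory containing the three files.
#' @param transpose Transpose from features x observations (default TRUE).
#' @return Dense numeric matrix, observations x features, with dimnames.
#' @export
read_matrix_mtx <- function(dir, transpose = TRUE) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("cannot read '%s': no such file", missing[1]), call. = FALSE)
  m <- as.matrix(Matrix::readMM(paths[1]))
  feats <- utils::read.delim(paths[2], header = FALSE)[[1]]
  cells <- utils::read.delim(paths[3], header = FALSE)[[1]]
  if (transpose) m <- t(m)
  if (nrow(m) != length(cells) || ncol(m) != length(feats))
    stop(sprintf(
      "MTX dimensions (%d x %d after orientation) do not match sidecars (%d barcodes, %d features); check --transpose",
      nrow(m), ncol(m), length(cells), length(feats)), call. = FALSE)
  dimnames(m) <- list(as.character(cells), as.character(feats))
  m
}

#' @rdname read_matrix_mtx
#' @param x Observations x features matrix to write.
#' @export
write_matrix_mtx <- function(x, dir, transpose = TRUE) {
  x <- as_num_matrix(x, "x")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- if (transpose) t(x) else x
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m), "generalMatrix"),
                              "TsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(colnames(x), file.path(dir, "features.tsv"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(rownames(x) %||% paste0("s", seq_len(nrow(x))),
                     file.path(dir, "barcodes.tsv"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read / write per-sample group labels as two-column TSV
#'
#' Columns: sample name, group label; no header.
#'
#' @param path File path.
#' @param labels Character vector of labels named by sample.
#' @return `read_labels_tsv()`: named character vector (names = samples).
#' @export
read_labels_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path),
                               call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop(sprintf("'%s' must have two columns: sample, label", path),
                         call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_labels_tsv
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample = names(labels) %||% seq_along(labels),
               label = as.character(labels)),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a covariance matrix as square CSV
#'
#' Square CSV with a header row of feature names (no row-name column).
#'
#' @param path File path.
#' @param sigma Symmetric matrix.
#' @param digits Significant digits written.
#' @export
read_cov_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  m
}

#' @rdname read_cov_csv
#' @export
write_cov_csv <- function(sigma, path, digits = 15) {
  sigma <- as_num_matrix(sigma, "sigma")
  utils::write.csv(signif(sigma, digits), path, row.names = FALSE)
  invisible(path)
}
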