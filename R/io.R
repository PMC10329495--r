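#' Read a modality matrix from disk
#'
#' Supported formats: dense CSV/TSV with a header row of feature names and a
#' first column of cell identifiers, or MatrixMarket `.mtx` with sidecar
#' `<stem>_rows.txt` / `<stem>_cols.txt` name files (one name per line).
#' Matrices are returned cells x features; use `transpose = TRUE` when the
#' file stores features in rows.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param transpose flip the on-disk orientation after reading.
#' @return dense numeric matrix with cell rownames and feature colnames.
#' @export
read_modality <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                          transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", tsv = "tsv", txt = "tsv", "csv")
  }
  if (format == "mtx") {
    M <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rf <- paste0(stem, "_rows.txt")
    cf <- paste0(stem, "_cols.txt")
    if (file.exists(rf)) rownames(M) <- readLines(rf)
    if (file.exists(cf)) colnames(M) <- readLines(cf)
  } else {
    dt <- data.table::fread(path, sep = if (format == "tsv") "\t" else ",",
                            header = TRUE, data.table = FALSE)
    ids <- as.character(dt[[1]])
    M <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(M) <- "double"
    rownames(M) <- ids
  }
  if (transpose) M <- t(M)
  if (is.null(rownames(M))) rownames(M) <- auto_ids(nrow(M))
  if (is.null(colnames(M))) colnames(M) <- auto_ids(ncol(M), "feature")
  if (anyDuplicated(rownames(M))) stop("duplicate cell identifiers in ", path)
  if (anyNA(M)) stop("NA/NaN entries in ", path)
  M
}

#' Write a modality matrix to disk
#'
#' Inverse of [read_modality()]. CSV/TSV writes cell identifiers in the
#' first column at full (17 significant digit) precision so a round trip is
#' bit-exact; MTX writes the matrix plus `_rows.txt` / `_cols.txt` sidecars.
#'
#' @param X matrix, cells in rows, with dimnames.
#' @param path output file path.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_modality <- function(X, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  check_matrix(X)
  if (is.null(rownames(X))) rownames(X) <- auto_ids(nrow(X))
  if (is.null(colnames(X))) colnames(X) <- auto_ids(ncol(X), "feature")
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(X), paste0(stem, "_rows.txt"))
    writeLines(colnames(X), paste0(stem, "_cols.txt"))
  } else {
    # 17 significant digits so the text round-trips doubles bit-exactly
    Xc <- matrix(sprintf("%.17g", X), nrow(X), dimnames = dimnames(X))
    df <- data.frame(cell_id = rownames(X), Xc, check.names = FALSE)
    data.table::fwrite(df, path, sep = if (format == "tsv") "\t" else ",",
                       quote = FALSE)
  }
  invisible(path)
}
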