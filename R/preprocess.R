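#' Z-score normalize a modality matrix
#'
#' Standardizes every feature (column) to mean 0 and standard deviation 1.
#' Zero-variance features cannot be standardized and are set to all zeros,
#' with a warning.
#'
#' @param X numeric matrix, cells in rows, features in columns.
#' @return A matrix of the same shape and dimnames.
#' @examples
#' X <- matrix(rnorm(20), 5, 4)
#' Z <- zscore_normalize(X)
#' colMeans(Z)  # ~0
#' @export
zscore_normalize <- function(X) {
  check_matrix(X)
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  zero <- s < .Machine$double.eps^0.5
  s[zero] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
  if (any(zero)) {
    Z[, zero] <- 0
    warning(sprintf("%d zero-variance feature(s) set to 0", sum(zero)))
  }
  dimnames(Z) <- dimnames(X)
  Z
}

#' Reduce a modality matrix by principal component analysis
#'
#' Projects cells onto the top principal components. With
#' `ncomp = "auto"` the dimension is `min(50, n - 1, d)`, the common
#' single-cell pipeline default. When the matrix already has `<= ncomp`
#' features (e.g. an ADT panel) it is returned unchanged. Component signs
#' follow a deterministic convention (the largest-magnitude loading of each
#' component is positive) so results are reproducible across platforms.
#'
#' @param X numeric matrix, cells in rows.
#' @param ncomp number of components to keep, or `"auto"`.
#' @return cells x ncomp matrix of principal component scores.
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' S <- pca_reduce(X, ncomp = 3)
#' dim(S)
#' @export
pca_reduce <- function(X, ncomp = "auto") {
  check_matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (identical(ncomp, "auto")) ncomp <- min(50L, n - 1L, d)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1L, d))
    stop("'ncomp' must be in [1, min(n - 1, d)]")
  if (d <= ncomp) return(X)  # low-dimensional modality: nothing to reduce
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = ncomp)
  flip <- vapply(seq_len(ncomp), function(j) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) -1 else 1
  }, numeric(1))
  S <- sweep(p$x[, seq_len(ncomp), drop = FALSE], 2, flip, "*")
  rownames(S) <- rownames(X)
  S
}

#' Normalize and reduce one modality
#'
#' Convenience wrapper applying [zscore_normalize()] then [pca_reduce()],
#' the preprocessing used before graph construction.
#'
#' @param X numeric matrix, cells in rows.
#' @param normalize z-score features first? Default `TRUE`.
#' @param ncomp passed to [pca_reduce()]; `NULL` skips the reduction.
#' @return preprocessed matrix, cells in rows.
#' @export
preprocess_modality <- function(X, normalize = TRUE, ncomp = "auto") {
  check_matrix(X)
  if (normalize) X <- suppressWarnings(zscore_normalize(X))
  if (!is.null(ncomp)) X <- pca_reduce(X, ncomp)
  X
}

#' Align modalities to a shared set of cells
#'
#' Restricts every modality to the intersection of their cell identifiers
#' (matrix rownames) and puts them in a common order (the order of the first
#' modality). Warns when cells are dropped; errors when fewer than two cells
#' are shared.
#'
#' @param modalities list of matrices, cells in rows, with rownames.
#' @return list of matrices with identical rownames in identical order.
#' @export
align_cells <- function(modalities) {
  stopifnot(is.list(modalities), length(modalities) >= 1)
  ids <- lapply(modalities, rownames)
  if (any(vapply(ids, is.null, logical(1))))
    stop("all modalities need rownames (cell identifiers) for alignment")
  common <- Reduce(intersect, ids)
  common <- ids[[1]][ids[[1]] %in% common]  # keep first modality's order
  if (length(common) < 2)
    stop("fewer than 2 cells shared across modalities")
  dropped <- sum(vapply(ids, function(x) length(setdiff(x, common)), numeric(1)))
  if (dropped > 0)
    warning(sprintf("%d cell(s) dropped during alignment", dropped))
  lapply(modalities, function(X) X[common, , drop = FALSE])
}
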