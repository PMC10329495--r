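#' Joint embedding and clustering of multi-omics single-cell data
#'
#' The full scHoML pipeline. Each modality (a cells x features matrix over
#' the same cells) is z-score normalized and reduced by PCA; first- and
#' second-order KNN graph Laplacians are built per modality; the
#' alternating fused-Laplacian optimization learns modality weights `mu`,
#' an order-mixing weight `lambda` and a common orthonormal embedding `H`;
#' finally cells are clustered by agglomerative hierarchical clustering on
#' an embedding distance, with the cluster number chosen automatically
#' (mean silhouette for small data sets, variance-ratio criterion for
#' large ones).
#'
#' @param modalities list of two or more numeric matrices, cells in rows.
#'   Matrices with rownames are aligned to their common cells; unnamed
#'   matrices must already have matching row order.
#' @param c embedding dimension; typically the expected number of cell
#'   types.
#' @param k KNN neighbor count; `NULL` (default) uses 10 for
#'   `n <= 2000` and 100 otherwise.
#' @param K candidate cluster numbers for automatic selection
#'   (default `2:10`).
#' @param max_order highest graph order fused (default 2).
#' @param sigma kernel width: `NULL` for the per-modality sample standard
#'   deviation, or a fixed positive value.
#' @param symmetrize KNN symmetrization, `"union"` or `"mutual"`.
#' @param normalize z-score features before PCA? Default `TRUE`.
#' @param ncomp PCA dimension per modality (`"auto"` = `min(50, n-1, d)`;
#'   `NULL` skips PCA).
#' @param distance clustering distance, `"correlation"` or `"l1"`.
#' @param criterion cluster-number criterion, `"auto"`, `"silhouette"` or
#'   `"variance_ratio"`.
#' @param linkage hierarchical linkage (default `"average"`).
#' @param max_iter,tol optimizer controls, see [fuse_laplacians()].
#' @param cluster run the clustering stage? `FALSE` returns the embedding
#'   only.
#' @return object of class `"schoml"`: list with `embedding` (n x c),
#'   `labels`, `k_selected`, `criterion_scores`, `criterion_used`,
#'   `lambda`, `mu`, `Lambda`, `objective_trace`, `n_iter`, `converged`,
#'   `sigma`, `k`, `distance`, `call`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset2(seed = 1)
#' fit <- schoml(list(ds$X1, ds$X2), c = 4)
#' fit
#' ari(ds$labels, fit$labels)
#' }
#' @export
schoml <- function(modalities, c, k = NULL, K = 2:10, max_order = 2,
                   sigma = NULL, symmetrize = c("union", "mutual"),
                   normalize = TRUE, ncomp = "auto",
                   distance = c("correlation", "l1"),
                   criterion = c("auto", "silhouette", "variance_ratio"),
                   linkage = "average",
                   max_iter = 100, tol = 1e-6, cluster = TRUE) {
  symmetrize <- match.arg(symmetrize)
  distance <- match.arg(distance)
  criterion <- match.arg(criterion)
  cl <- match.call()
  if (is.matrix(modalities)) modalities <- list(modalities)
  stopifnot(is.list(modalities), length(modalities) >= 1)
  lapply(modalities, check_matrix, name = "modalities[[.]]")
  named <- !vapply(modalities, function(X) is.null(rownames(X)), logical(1))
  if (all(named) && length(modalities) > 1) {
    modalities <- align_cells(modalities)
  } else if (length(unique(vapply(modalities, nrow, integer(1)))) != 1) {
    stop("modalities have different cell counts and no rownames to align by")
  }
  n <- nrow(modalities[[1]])
  ids <- rownames(modalities[[1]])
  if (is.null(ids)) ids <- auto_ids(n)

  prep <- lapply(modalities, preprocess_modality,
                 normalize = normalize, ncomp = ncomp)
  stack <- laplacian_stack(prep, k = k, max_order = max_order,
                           sigma = sigma, symmetrize = symmetrize)
  fit <- fuse_laplacians(stack, c = c, max_iter = max_iter, tol = tol)
  H <- fit$H
  rownames(H) <- ids

  out <- list(embedding = H, lambda = fit$lambda, mu = fit$mu,
              Lambda = fit$Lambda, W_factor = fit$W_factor,
              objective_trace = fit$objective_trace, n_iter = fit$n_iter,
              converged = fit$converged, sigma = stack$sigma, k = stack$k,
              distance = distance, labels = NULL, k_selected = NULL,
              criterion_scores = NULL, criterion_used = NULL,
              call = cl)
  if (cluster) {
    cres <- cluster_embedding(H, K = K, distance = distance,
                              criterion = criterion, linkage = linkage)
    out$labels <- cres$labels
    names(out$labels) <- ids
    out$k_selected <- cres$k
    out$criterion_scores <- cres$criterion_scores
    out$criterion_used <- cres$criterion_used
  }
  class(out) <- "schoml"
  out
}

#' @export
print.schoml <- function(x, ...) {
  cat(sprintf("scHoML fit: %d cells, %d modalities, embedding dimension %d\n",
              nrow(x$embedding), length(x$mu), ncol(x$embedding)))
  cat(sprintf("  optimizer: %d iteration(s), %sconverged; objective %.6g -> %.6g\n",
              x$n_iter, if (x$converged) "" else "NOT ",
              x$objective_trace[1], tail(x$objective_trace, 1)))
  cat("  modality weights mu:", paste(signif(x$mu, 4), collapse = ", "),
      "; order weight lambda:", signif(x$lambda, 4), "\n")
  if (!is.null(x$labels)) {
    cat(sprintf("  clusters: %d (selected by %s criterion)\n",
                x$k_selected, x$criterion_used))
    print(table(cluster = x$labels))
  }
  invisible(x)
}

#' @export
summary.schoml <- function(object, ...) {
  structure(list(fit = object), class = "summary.schoml")
}

#' @export
print.summary.schoml <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat("  Lambda (spectral weights):",
      paste(signif(f$Lambda, 3), collapse = ", "), "\n")
  cat("  graph: k =", f$k, "; sigma =", paste(signif(f$sigma, 4), collapse = ", "), "\n")
  if (!is.null(f$criterion_scores)) {
    cat("  cluster-number scores:\n")
    print(signif(f$criterion_scores, 4))
  }
  invisible(x)
}

#' Model parameters of a scHoML fit
#'
#' Returns the learned fusion parameters: the modality weights `mu`
#' (simplex), the order-mixing weight `lambda` and the spectral weights
#' `Lambda` of the fused-Laplacian factorization.
#'
#' @param object a `"schoml"` fit.
#' @param ... unused.
#' @return named list with `lambda`, `mu`, `Lambda`.
#' @export
coef.schoml <- function(object, ...) {
  list(lambda = object$lambda, mu = object$mu, Lambda = object$Lambda)
}

#' Plot a scHoML embedding
#'
#' Scatter plot of the first two embedding coordinates (or all pairs when
#' `pairs = TRUE`), colored by the assigned cluster when available.
#'
#' @param x a `"schoml"` fit.
#' @param pairs plot all coordinate pairs instead of the first two.
#' @param ... passed to [graphics::plot()] / [graphics::pairs()].
#' @return `x`, invisibly.
#' @export
plot.schoml <- function(x, pairs = FALSE, ...) {
  H <- x$embedding
  col <- if (!is.null(x$labels)) {
    pal <- grDevices::hcl.colors(max(3, length(unique(x$labels))), "Dark 3")
    pal[as.integer(factor(x$labels))]
  } else "grey30"
  if (pairs && ncol(H) > 2) {
    graphics::pairs(H, col = col, pch = 19, ...)
  } else {
    graphics::plot(H[, 1], H[, 2], col = col, pch = 19,
                   xlab = "embedding 1", ylab = "embedding 2", ...)
  }
  invisible(x)
}
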