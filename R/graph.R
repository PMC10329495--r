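#' K-nearest-neighbor Gaussian affinity matrix
#'
#' Builds the first-order adjacency matrix of a modality: cells j and k are
#' connected when one lies among the other's `k` nearest neighbors
#' (`symmetrize = "union"`, the default, keeps the matrix symmetric; use
#' `"mutual"` to require both directions), and connected pairs are weighted
#' by the Gaussian kernel `exp(-||x_j - x_k||^2 / (2 sigma^2))`. The
#' diagonal is zero.
#'
#' @param X numeric matrix, cells in rows (typically preprocessed).
#' @param k neighbor count, `1 <= k < n`. Default: 10 for `n <= 2000`,
#'   else 100.
#' @param sigma kernel width. `NULL` (default) uses the sample standard
#'   deviation of all entries of `X`.
#' @param symmetrize `"union"` or `"mutual"`.
#' @return symmetric n x n affinity matrix with zero diagonal, entries in
#'   \[0, 1\], with attribute `"sigma"`.
#' @export
knn_affinity <- function(X, k = NULL, sigma = NULL,
                         symmetrize = c("union", "mutual")) {
  symmetrize <- match.arg(symmetrize)
  check_matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 cells")
  if (is.null(k)) k <- default_k(n)
  k <- as.integer(k)
  if (k < 1 || k >= n) stop("'k' must satisfy 1 <= k < n")
  if (is.null(sigma)) sigma <- stats::sd(X)
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate input: kernel width sigma is not positive (constant data?)")
  D2 <- as.matrix(stats::dist(X))^2
  nn <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    ord <- order(D2[j, ])            # stable: ties broken by cell index
    ord <- ord[ord != j]
    nn[j, ord[seq_len(k)]] <- TRUE   # k nearest neighbors of cell j
  }
  conn <- if (symmetrize == "union") nn | t(nn) else nn & t(nn)
  A <- exp(-D2 / (2 * sigma^2)) * conn
  diag(A) <- 0
  A <- (A + t(A)) / 2
  dimnames(A) <- list(rownames(X), rownames(X))
  attr(A, "sigma") <- sigma
  A
}

#' High-order affinity matrix from a lower-order adjacency
#'
#' Lifts an order-(i-1) adjacency to order i: vertices j and k are similar
#' at the next order when their adjacency rows are similar, i.e.
#' `exp(-||w_j - w_k||^2 / (2 sigma^2))` whenever the two rows share at
#' least one commonly-connected vertex (including j and k themselves), and
#' 0 otherwise. The diagonal is forced to zero.
#'
#' @param W symmetric nonnegative adjacency matrix with zero diagonal.
#' @param sigma kernel width; typically the same value used at order 1.
#' @return symmetric n x n affinity with zero diagonal.
#' @export
high_order_affinity <- function(W, sigma) {
  check_matrix(W)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-8)
    stop("'W' must be a symmetric square matrix")
  if (any(diag(W) != 0)) stop("'W' must have a zero diagonal")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive")
  D2 <- as.matrix(stats::dist(W))^2
  P <- (W > 0) * 1
  share <- (P %*% P) > 0   # exists t with w_jt > 0 and w_kt > 0
  A <- exp(-D2 / (2 * sigma^2)) * share
  diag(A) <- 0
  A <- (A + t(A)) / 2
  attributes(A) <- list(dim = dim(A), dimnames = dimnames(W)[1:2])
  A
}

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^{-1/2} W D^{-1/2}` with `D` the diagonal degree matrix. The
#' result is symmetric positive semi-definite with eigenvalues in \[0, 2\]
#' and unit diagonal on non-isolated vertices. Isolated vertices (zero
#' degree) get an identity row/column, the limit of the formula, which
#' keeps the matrix PSD without dividing by zero.
#'
#' @param W symmetric nonnegative affinity matrix with zero diagonal.
#' @return n x n normalized Laplacian matrix.
#' @export
normalized_laplacian <- function(W) {
  check_matrix(W)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-8)
    stop("'W' must be a symmetric square matrix")
  n <- nrow(W)
  d <- rowSums(W)
  ok <- d > .Machine$double.eps
  s <- ifelse(ok, 1 / sqrt(d), 0)
  L <- diag(n) - (outer(s, s) * W)
  # isolated vertices: identity row/column
  L[!ok, ] <- 0
  L[, !ok] <- 0
  diag(L)[!ok] <- 1
  L <- (L + t(L)) / 2
  attributes(L) <- list(dim = dim(L), dimnames = dimnames(W)[1:2])
  L
}

#' Build the multi-modal multi-order Laplacian stack
#'
#' For each of the V modalities, builds the KNN affinity graph, lifts it to
#' the requested orders, and returns the U x V normalized Laplacians used
#' by the fusion optimizer. The kernel width of each modality is resolved
#' once at order 1 (sample standard deviation of the preprocessed matrix by
#' default) and reused at higher orders.
#'
#' @param modalities list of matrices, cells in rows, equal cell counts
#'   (typically the output of [preprocess_modality()] / [align_cells()]).
#' @param k neighbor count; `NULL` for the n-dependent default.
#' @param max_order highest adjacency order U (default 2).
#' @param sigma `NULL` (per-modality sample standard deviation) or a fixed
#'   positive value, recycled over modalities.
#' @param symmetrize passed to [knn_affinity()].
#' @return an object of class `"laplacian_stack"`: a list with elements
#'   `L` (list of V lists of U Laplacians), `sigma`, `k`, `n`, `V`, `U`,
#'   `cell_ids`.
#' @export
laplacian_stack <- function(modalities, k = NULL, max_order = 2,
                            sigma = NULL, symmetrize = c("union", "mutual")) {
  symmetrize <- match.arg(symmetrize)
  stopifnot(is.list(modalities), length(modalities) >= 1)
  ns <- vapply(modalities, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stop("modalities have different cell counts; align them first")
  n <- ns[1]
  U <- as.integer(max_order)
  if (U < 1) stop("'max_order' must be >= 1")
  if (is.null(k)) k <- default_k(n)
  sig <- if (is.null(sigma)) rep(NA_real_, length(modalities))
         else rep_len(sigma, length(modalities))
  L <- vector("list", length(modalities))
  for (p in seq_along(modalities)) {
    X <- modalities[[p]]
    s <- if (is.na(sig[p])) NULL else sig[p]
    W <- knn_affinity(X, k = k, sigma = s, symmetrize = symmetrize)
    sig[p] <- attr(W, "sigma")
    Lp <- vector("list", U)
    Lp[[1]] <- normalized_laplacian(W)
    if (U >= 2) {
      for (i in 2:U) {
        W <- high_order_affinity(W, sigma = sig[p])
        Lp[[i]] <- normalized_laplacian(W)
      }
    }
    L[[p]] <- Lp
  }
  structure(list(L = L, sigma = sig, k = as.integer(k), n = n,
                 V = length(modalities), U = U,
                 cell_ids = rownames(modalities[[1]])),
            class = "laplacian_stack")
}

#' @export
print.laplacian_stack <- function(x, ...) {
  cat(sprintf("Laplacian stack: %d modalit%s x %d order%s, n = %d cells\n",
              x$V, if (x$V == 1) "y" else "ies",
              x$U, if (x$U == 1) "" else "s", x$n))
  cat("  k =", x$k, "; sigma =", signif(x$sigma, 4), "\n")
  invisible(x)
}
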