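#' Correlation distance between embedded cells
#'
#' `Dis(s, t) = 1 - r(h_s, h_t)` where `r` is the Pearson correlation of
#' the row-centered embedding rows. Entries lie in \[0, 2\]; the diagonal
#' is zero. Rows with zero variance have no defined correlation; their
#' distance to every other cell is set to 1, with a warning.
#'
#' @param H numeric matrix, cells in rows (embedding coordinates).
#' @return symmetric n x n distance matrix.
#' @export
correlation_distance <- function(H) {
  check_matrix(H)
  if (ncol(H) < 2) stop("correlation distance needs at least 2 columns")
  Hc <- H - rowMeans(H)
  nr <- sqrt(rowSums(Hc^2))
  flat <- nr < .Machine$double.eps^0.5
  nr[flat] <- 1
  R <- tcrossprod(Hc / nr)
  R[R > 1] <- 1
  R[R < -1] <- -1
  D <- 1 - R
  if (any(flat)) {
    warning(sprintf("%d constant embedding row(s): distance set to 1", sum(flat)))
    D[flat, ] <- 1
    D[, flat] <- 1
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(H), rownames(H))
  D
}

#' L1 (Manhattan) distance between embedded cells
#'
#' `Dis(s, t) = sum_k |h_s(k) - h_t(k)|`.
#'
#' @param H numeric matrix, cells in rows.
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
l1_distance <- function(H) {
  check_matrix(H)
  D <- as.matrix(stats::dist(H, method = "manhattan"))
  dimnames(D) <- list(rownames(H), rownames(H))
  D
}

embedding_distance <- function(H, distance = c("correlation", "l1")) {
  distance <- match.arg(distance)
  if (distance == "correlation") correlation_distance(H) else l1_distance(H)
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Average-linkage agglomeration (default) on a precomputed distance
#' matrix, cut at `k` clusters. Average linkage is used because the
#' correlation distance is not Euclidean; `"ward.D2"` is available for
#' metric (L1/Euclidean-like) inputs.
#'
#' @param D symmetric distance matrix.
#' @param k number of clusters, `2 <= k <= n`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return integer cluster labels of length n.
#' @export
hcluster_labels <- function(D, k, linkage = "average") {
  k <- as.integer(k)
  n <- nrow(as.matrix(D))
  if (k < 1 || k > n) stop("'k' out of range")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  stats::cutree(hc, k = k)
}

#' Select the cluster number by mean silhouette
#'
#' For every candidate `k`, cells are clustered by cutting one
#' average-linkage tree and the mean silhouette width
#' `(b - a) / max(a, b)` over all cells is computed on the same distance
#' matrix (members of singleton clusters contribute 0). The `k`
#' maximizing the mean silhouette wins; ties go to the smallest `k`.
#'
#' @param D symmetric distance matrix.
#' @param K integer vector of candidate cluster numbers (subset of
#'   `[2, n - 1]`).
#' @param linkage linkage method for the tree.
#' @return list with `k` (the selected number) and `scores` (named vector
#'   of mean silhouettes per candidate).
#' @export
select_k_silhouette <- function(D, K = 2:10, linkage = "average") {
  D <- as.matrix(D)
  n <- nrow(D)
  K <- sort(unique(as.integer(K)))
  if (length(K) == 0) stop("empty candidate set")
  if (any(K < 2 | K > n - 1)) stop("candidates must lie in [2, n - 1]")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  scores <- vapply(K, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(lab, dmatrix = D)[, "sil_width"])
  }, numeric(1))
  names(scores) <- K
  list(k = K[which.max(scores)], scores = scores)
}

# Calinski-Harabasz variance ratio of one labeling of the rows of H
variance_ratio_score <- function(H, labels) {
  n <- nrow(H)
  k <- length(unique(labels))
  center <- colMeans(H)
  ssb <- 0
  ssw <- 0
  for (q in unique(labels)) {
    Xq <- H[labels == q, , drop = FALSE]
    cq <- colMeans(Xq)
    ssb <- ssb + nrow(Xq) * sum((cq - center)^2)
    ssw <- ssw + sum(sweep(Xq, 2, cq, "-")^2)
  }
  if (ssw <= .Machine$double.eps) return(Inf)  # perfectly compact clusters
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Select the cluster number by the variance-ratio criterion
#'
#' For every candidate `k`, cells are clustered on the distance matrix and
#' the Calinski-Harabasz statistic -- between-cluster scatter trace over
#' `k - 1` divided by within-cluster scatter trace over `n - k` -- is
#' computed on the embedding coordinates. Perfectly compact clusterings
#' (zero within-cluster scatter) score `+Inf`. The maximizing `k` wins.
#'
#' @param H embedding matrix, cells in rows.
#' @param K candidate cluster numbers.
#' @param D optional precomputed distance matrix; by default the
#'   correlation distance of `H`.
#' @param linkage linkage method for the tree.
#' @return list with `k` and `scores` as in [select_k_silhouette()].
#' @export
select_k_variance_ratio <- function(H, K = 2:10, D = NULL,
                                    linkage = "average") {
  check_matrix(H)
  n <- nrow(H)
  K <- sort(unique(as.integer(K)))
  if (length(K) == 0) stop("empty candidate set")
  if (any(K < 2 | K > n - 1)) stop("candidates must lie in [2, n - 1]")
  if (is.null(D)) D <- correlation_distance(H)
  hc <- stats::hclust(stats::as.dist(as.matrix(D)), method = linkage)
  scores <- vapply(K, function(k) {
    variance_ratio_score(H, stats::cutree(hc, k = k))
  }, numeric(1))
  names(scores) <- K
  list(k = K[which.max(scores)], scores = scores)
}

#' Cluster an embedding with automatic cluster-number selection
#'
#' The full clustering stage: build the chosen cell-cell distance on the
#' embedding, pick the cluster number from the candidates by the
#' regime-appropriate criterion (mean silhouette when `n <= 500`,
#' variance ratio otherwise, unless forced), and cut the tree at the
#' selected number.
#'
#' @param H embedding matrix, cells in rows.
#' @param K candidate cluster numbers (default `2:10`, intersected with
#'   `[2, n - 1]`).
#' @param distance `"correlation"` (default) or `"l1"`.
#' @param criterion `"auto"` (regime rule), `"silhouette"` or
#'   `"variance_ratio"`.
#' @param linkage linkage method for the tree.
#' @return object of class `"schoml_clustering"`: list with `labels`,
#'   `k`, `criterion_scores`, `criterion_used`, `distance`.
#' @export
cluster_embedding <- function(H, K = 2:10,
                              distance = c("correlation", "l1"),
                              criterion = c("auto", "silhouette",
                                            "variance_ratio"),
                              linkage = "average") {
  distance <- match.arg(distance)
  criterion <- match.arg(criterion)
  check_matrix(H)
  n <- nrow(H)
  K <- intersect(sort(unique(as.integer(K))), 2:(n - 1))
  if (length(K) == 0) stop("no valid cluster-number candidates")
  if (criterion == "auto")
    criterion <- if (n <= 500) "silhouette" else "variance_ratio"
  D <- embedding_distance(H, distance)
  sel <- if (criterion == "silhouette") {
    select_k_silhouette(D, K, linkage = linkage)
  } else {
    select_k_variance_ratio(H, K, D = D, linkage = linkage)
  }
  labels <- hcluster_labels(D, sel$k, linkage = linkage)
  structure(list(labels = labels, k = sel$k,
                 criterion_scores = sel$scores,
                 criterion_used = criterion, distance = distance),
            class = "schoml_clustering")
}

#' @export
print.schoml_clustering <- function(x, ...) {
  cat(sprintf("Hierarchical clustering: k = %d (%s criterion, %s distance)\n",
              x$k, x$criterion_used, x$distance))
  print(table(cluster = x$labels))
  invisible(x)
}
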