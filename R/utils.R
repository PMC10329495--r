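# Internal numerical helpers shared across modules.

# Eigenvectors of the c algebraically smallest eigenvalues of a symmetric
# matrix, columns in ascending eigenvalue order, with a deterministic sign
# convention: each vector's largest-magnitude entry is positive (first index
# on ties). Returns list(vectors, values).
eig_smallest <- function(M, c) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), c >= 1, c <= nrow(M))
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  idx <- seq(ncol(M), by = -1L, length.out = c)  # eigen() sorts descending
  V <- e$vectors[, idx, drop = FALSE]
  for (j in seq_len(c)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(vectors = V, values = e$values[idx])
}

# Exact minimizer of  mu' Q mu + f' mu  over the probability simplex
# (sum(mu) = 1, mu >= 0), Q symmetric PSD. Enumerates active sets: for every
# nonempty support S the equality-constrained KKT system is solved (least-norm
# solution via pseudo-inverse when singular), infeasible candidates are
# discarded, and the best feasible candidate wins. Objective ties within 1e-10
# are broken toward the most uniform (maximum entropy) solution.
simplex_qp <- function(Q, f) {
  V <- nrow(Q)
  stopifnot(ncol(Q) == V, length(f) == V)
  if (V == 1L) return(1)
  best <- NULL
  best_obj <- Inf
  qobj <- function(mu) drop(crossprod(mu, Q %*% mu)) + sum(f * mu)
  for (m in seq_len(V)) {
    for (S in combn(V, m, simplify = FALSE)) {
      K <- rbind(cbind(2 * Q[S, S, drop = FALSE], rep(1, m)),
                 c(rep(1, m), 0))
      rhs <- c(-f[S], 1)
      sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
      if (is.null(sol) || !all(is.finite(sol))) sol <- drop(MASS::ginv(K) %*% rhs)
      mu <- numeric(V)
      mu[S] <- sol[seq_len(m)]
      if (any(mu < -1e-9)) next
      mu[mu < 0] <- 0
      mu <- mu / sum(mu)
      o <- qobj(mu)
      if (o < best_obj - 1e-10) {
        best_obj <- o
        best <- mu
      } else if (o < best_obj + 1e-10 &&
                 sum((mu - 1 / V)^2) < sum((best - 1 / V)^2)) {
        best <- mu
      }
    }
  }
  best
}

# shared argument checks
check_matrix <- function(X, name = deparse(substitute(X))) {
  if (!is.matrix(X) || !is.numeric(X))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (anyNA(X))
    stop(sprintf("'%s' contains NA/NaN entries", name), call. = FALSE)
  invisible(X)
}

default_k <- function(n) if (n <= 2000) 10L else 100L

# cell ids for unlabeled matrices
auto_ids <- function(n, prefix = "cell") sprintf("%s_%d", prefix, seq_len(n))
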