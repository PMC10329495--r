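# Shared fixtures and independent brute-force oracles used across tests.

# random orthonormal n x c matrix
rand_orthonormal <- function(n, c) qr.Q(qr(matrix(rnorm(n * c), n, c)))

# small random Laplacian stack built from random modality matrices
rand_stack <- function(n = 12, V = 2, U = 2, k = 3, seed = 1) {
  set.seed(seed)
  mods <- lapply(seq_len(V), function(p) matrix(rnorm(n * 5), n, 5))
  laplacian_stack(mods, k = k, max_order = U)
}

# random fusion state respecting all constraints
rand_state <- function(n, c, V, seed = 1) {
  set.seed(seed)
  mu <- runif(V); mu <- mu / sum(mu)
  list(lambda = runif(1), mu = mu, Lambda = runif(c),
       W = rand_orthonormal(n, c), H = rand_orthonormal(n, c))
}

# well-separated Gaussian blobs; returns list(X, labels)
make_blobs <- function(n_per = 10, centers = rbind(c(0, 0), c(10, 10), c(-10, 10)),
                       sd = 0.3, d = ncol(centers)) {
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(q)
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per, d), 2, centers[q, ], "+")))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# brute-force first-order KNN affinity (direct transcription, double loop)
knn_affinity_oracle <- function(X, k, sigma, symmetrize = "union") {
  n <- nrow(X)
  D2 <- matrix(0, n, n)
  for (j in 1:n) for (l in 1:n) D2[j, l] <- sum((X[j, ] - X[l, ])^2)
  nn <- matrix(FALSE, n, n)
  for (j in 1:n) {
    others <- setdiff(order(D2[j, ]), j)
    nn[j, others[seq_len(k)]] <- TRUE
  }
  A <- matrix(0, n, n)
  for (j in 1:n) for (l in 1:n) {
    conn <- if (symmetrize == "union") nn[j, l] || nn[l, j] else nn[j, l] && nn[l, j]
    if (j != l && conn) A[j, l] <- exp(-D2[j, l] / (2 * sigma^2))
  }
  A
}

# brute-force high-order affinity (direct double-loop transcription)
high_order_oracle <- function(W, sigma) {
  n <- nrow(W)
  A <- matrix(0, n, n)
  for (j in 1:n) for (l in 1:n) {
    if (j == l) next
    shares <- any(W[j, ] > 0 & W[l, ] > 0)
    if (shares) A[j, l] <- exp(-sum((W[j, ] - W[l, ])^2) / (2 * sigma^2))
  }
  A
}

# from-scratch mean silhouette of a labeling on distance matrix D
silhouette_oracle <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in 1:n) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, setdiff(own, i)]) / (length(own) - 1)
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(J) {
      mean(D[i, labels == J])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# variance-ratio criterion via per-dimension one-way ANOVA sums of squares
variance_ratio_aov_oracle <- function(H, labels) {
  n <- nrow(H); k <- length(unique(labels))
  g <- factor(labels)
  ss <- vapply(seq_len(ncol(H)), function(j) {
    a <- anova(stats::lm(H[, j] ~ g))
    c(between = a$`Sum Sq`[1], within = a$`Sum Sq`[2])
  }, numeric(2))
  (sum(ss["between", ]) / (k - 1)) / (sum(ss["within", ]) / (n - k))
}

# naive average-linkage agglomeration returning labels at k clusters
average_linkage_oracle <- function(D, k) {
  n <- nrow(D)
  groups <- as.list(1:n)
  while (length(groups) > k) {
    m <- length(groups)
    best <- c(Inf, 0, 0)
    for (a in 1:(m - 1)) for (b in (a + 1):m) {
      d <- mean(D[groups[[a]], groups[[b]]])
      if (d < best[1]) best <- c(d, a, b)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  labels <- integer(n)
  for (q in seq_along(groups)) labels[groups[[q]]] <- q
  labels
}

# Eq.(5)-style objective computed naively from raw state (independent of
# the package's fusion_objective)
naive_objective <- function(state, Ls) {
  n <- nrow(state$W)
  L1 <- Reduce(`+`, Map(`*`, lapply(Ls, `[[`, 1), state$mu))
  L2 <- Reduce(`+`, Map(`*`, lapply(Ls, `[[`, 2), state$mu))
  Lf <- state$lambda * L1 + (1 - state$lambda) * L2
  M <- diag(n) - state$W %*% diag(state$Lambda, ncol(state$W)) %*% t(state$W)
  sum(diag(t(state$H) %*% M %*% state$H)) + sum((M - Lf)^2)
}

# simplex lattice with the given step (all nonneg integer combos summing right)
simplex_lattice <- function(V, step = 0.05) {
  m <- round(1 / step)
  grid <- expand.grid(rep(list(0:m), V - 1))
  grid <- grid[rowSums(grid) <= m, , drop = FALSE]
  t(apply(grid, 1, function(r) c(r, m - sum(r)) / m))
}
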