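# internal update steps are reached via ::: ; they are exercised end-to-end
# through fuse_laplacians() as well.

obj_fn <- function(state, Ls) scHoML:::fusion_objective(state, Ls)

test_that("objective matches a naive evaluation and its Lambda = 0 limit", {
  st <- rand_stack(n = 10, V = 2, seed = 3)
  state <- rand_state(10, 3, 2, seed = 4)
  expect_equal(obj_fn(state, st$L), naive_objective(state, st$L),
               tolerance = 1e-10)
  # Lambda = 0: the trace term is tr(H'H) = c
  state0 <- state
  state0$Lambda <- rep(0, 3)
  L1 <- Reduce(`+`, Map(`*`, lapply(st$L, `[[`, 1), state0$mu))
  L2 <- Reduce(`+`, Map(`*`, lapply(st$L, `[[`, 2), state0$mu))
  Lf <- state0$lambda * L1 + (1 - state0$lambda) * L2
  expect_equal(obj_fn(state0, st$L), 3 + sum((diag(10) - Lf)^2),
               tolerance = 1e-10)
  # nonnegative on random valid states
  for (s in 1:5)
    expect_gte(obj_fn(rand_state(10, 3, 2, seed = s), st$L), 0)
})

test_that("lambda update solves its 1-D problem exactly", {
  # identical mixed orders: a = 0, lambda unchanged
  st <- rand_stack(n = 10, V = 1, seed = 5)
  Ls <- list(list(st$L[[1]][[1]], st$L[[1]][[1]]))
  state <- rand_state(10, 2, 1, seed = 6)
  expect_equal(scHoML:::update_lambda(state, Ls), state$lambda)

  # random instances: closed form beats a 1e-4 grid scan
  for (seed in 1:5) {
    st <- rand_stack(n = 8, V = 2, seed = seed)
    state <- rand_state(8, 2, 2, seed = seed + 100)
    lam <- scHoML:::update_lambda(state, st$L)
    expect_gte(lam, 0); expect_lte(lam, 1)
    grid <- seq(0, 1, by = 1e-4)
    vals <- vapply(grid, function(l) {
      s <- state; s$lambda <- l; obj_fn(s, st$L)
    }, numeric(1))
    s <- state; s$lambda <- lam
    expect_lte(obj_fn(s, st$L), min(vals) + 1e-10)
  }
})

test_that("W update minimizes tr(Lambda W' B W) over orthonormal W", {
  # eigenvector extraction: smallest-c eigenvectors of a diagonal matrix
  e <- scHoML:::eig_smallest(diag(c(1, 2, 3)), 2)
  expect_equal(abs(e$vectors), cbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(e$values, c(1, 2))

  # update never increases the objective, including with unsorted Lambda
  for (seed in 1:5) {
    st <- rand_stack(n = 10, V = 2, seed = seed)
    state <- rand_state(10, 3, 2, seed = seed + 50)
    before <- obj_fn(state, st$L)
    state$W <- scHoML:::update_W_factor(state, st$L)
    after <- obj_fn(state, st$L)
    expect_lte(after, before + 1e-9)
    expect_equal(crossprod(state$W), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("Lambda update beats per-coordinate grid scans and clamps to [0,1]", {
  for (seed in 1:5) {
    st <- rand_stack(n = 10, V = 2, seed = seed)
    state <- rand_state(10, 3, 2, seed = seed + 10)
    lam_new <- scHoML:::update_Lambda(state, st$L)
    expect_true(all(lam_new >= 0 & lam_new <= 1))
    before <- obj_fn(state, st$L)
    s <- state; s$Lambda <- lam_new
    after <- obj_fn(s, st$L)
    expect_lte(after, before + 1e-9)
    # each coordinate beats a fine grid scan of its own 1-D problem
    for (i in 1:3) {
      grid <- seq(0, 1, by = 1e-4)
      vals <- vapply(grid, function(g) {
        s2 <- s; s2$Lambda[i] <- g; obj_fn(s2, st$L)
      }, numeric(1))
      expect_lte(after, min(vals) + 1e-9)
    }
  }
})

test_that("H update attains the sum of the c smallest eigenvalues", {
  for (seed in 1:5) {
    st <- rand_stack(n = 10, V = 2, seed = seed)
    state <- rand_state(10, 3, 2, seed = seed + 20)
    state$H <- scHoML:::update_H(state, st$L)
    expect_equal(crossprod(state$H), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    M <- diag(10) - state$W %*% (state$Lambda * t(state$W))
    trace_val <- sum(diag(crossprod(state$H, M %*% state$H)))
    ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(trace_val, sum(ev[1:3]), tolerance = 1e-8)
  }
  # Lambda = I with c columns: H spans col(W), trace term 0
  st <- rand_stack(n = 10, V = 2, seed = 1)
  state <- rand_state(10, 3, 2, seed = 2)
  state$Lambda <- rep(1, 3)
  H <- scHoML:::update_H(state, st$L)
  M <- diag(10) - tcrossprod(state$W)
  expect_lt(sum(diag(crossprod(H, M %*% H))), 1e-8)
})

test_that("mu update solves the simplex QP", {
  # V = 1: the simplex is a point
  st <- rand_stack(n = 10, V = 1, seed = 9)
  Ls <- list(list(st$L[[1]][[1]], st$L[[1]][[2]]))
  state <- rand_state(10, 2, 1, seed = 9)
  expect_equal(scHoML:::update_mu(state, Ls), 1)

  # identical modalities: symmetric tie broken to the uniform weights
  st <- rand_stack(n = 10, V = 1, seed = 10)
  Ls <- list(st$L[[1]], st$L[[1]])
  state <- rand_state(10, 2, 2, seed = 10)
  expect_equal(scHoML:::update_mu(state, Ls), c(0.5, 0.5), tolerance = 1e-8)

  # V = 3: QP minimizer beats every point of a 0.05-step simplex lattice
  for (seed in 1:3) {
    st <- rand_stack(n = 10, V = 3, seed = seed + 30)
    state <- rand_state(10, 3, 3, seed = seed + 30)
    mu <- scHoML:::update_mu(state, st$L)
    expect_equal(sum(mu), 1, tolerance = 1e-10)
    expect_true(all(mu >= -1e-12))
    s <- state; s$mu <- mu
    best <- obj_fn(s, st$L)
    lattice <- simplex_lattice(3, 0.05)
    for (r in seq_len(nrow(lattice))) {
      s$mu <- lattice[r, ]
      expect_lte(best, obj_fn(s, st$L) + 1e-9)
    }
  }
})

test_that("fit decreases the objective monotonically to a nonnegative limit", {
  for (seed in 1:10) {
    st <- rand_stack(n = 12, V = 2, seed = seed)
    fit <- fuse_laplacians(st, c = 3, max_iter = 30)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * (1 + abs(tr[-length(tr)]))))
    expect_gte(tr[length(tr)], 0)
    expect_equal(crossprod(fit$H), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(crossprod(fit$W_factor), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sum(fit$mu), 1, tolerance = 1e-10)
    expect_true(all(fit$Lambda >= 0 & fit$Lambda <= 1))
  }
})

test_that("spectral initialization makes the fit deterministic", {
  st <- rand_stack(n = 12, V = 2, seed = 13)
  f1 <- fuse_laplacians(st, c = 2)
  f2 <- fuse_laplacians(st, c = 2)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("two separated blobs in both modalities are linearly separated by H", {
  set.seed(21)
  b1 <- make_blobs(n_per = 10, centers = rbind(c(0, 0, 0), c(8, 8, 8)), sd = 0.4)
  b2 <- make_blobs(n_per = 10, centers = rbind(c(-5, 0), c(5, 0)), sd = 0.4)
  st <- laplacian_stack(list(b1$X, b2$X), k = 4)
  fit <- fuse_laplacians(st, c = 2)
  lab <- hcluster_labels(l1_distance(fit$H), 2)
  expect_equal(ari(b1$labels, lab), 1)
})

test_that("single modality, single order reduces to spectral embedding", {
  set.seed(22)
  X <- make_blobs(n_per = 8, centers = rbind(c(0, 0), c(6, 6)), sd = 0.5)$X
  st <- laplacian_stack(list(X), k = 3, max_order = 1)
  fit <- fuse_laplacians(st, c = 2, max_iter = 200)
  L <- st$L[[1]][[1]]
  Hs <- scHoML:::eig_smallest(L, 2)$vectors
  # compare the spanned subspaces through their projectors
  P1 <- tcrossprod(fit$H)
  P2 <- tcrossprod(Hs)
  expect_lt(max(abs(P1 - P2)), 1e-4)
})
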