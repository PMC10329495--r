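# Alternating optimization of the fused-Laplacian objective
#
#   min  tr(H'(I - W L W')H) + || I - W L W' - (lambda*Lmu1 + (1-lambda)*Lmu2) ||_F^2
#
# over lambda in [0,1], the simplex vector mu of modality weights, the
# orthonormal factor W (n x c), the diagonal 0 <= Lambda <= 1 and the
# orthonormal embedding H (n x c). Each block update below is the exact
# minimizer of the objective in its own variable, so the objective is
# non-increasing along the iteration.

# sum_p mu_p * L_p^(order)
mix_laplacian <- function(Ls, mu, order) {
  out <- mu[1] * Ls[[1]][[order]]
  if (length(Ls) > 1)
    for (p in 2:length(Ls)) out <- out + mu[p] * Ls[[p]][[order]]
  out
}

# Eq. (5) objective for the current state
fusion_objective <- function(state, Ls) {
  n <- nrow(state$W)
  Lf <- state$lambda * mix_laplacian(Ls, state$mu, 1) +
    (1 - state$lambda) * mix_laplacian(Ls, state$mu, 2)
  M <- diag(n) - state$W %*% (state$Lambda * t(state$W))
  sum(diag(crossprod(state$H, M %*% state$H))) + sum((M - Lf)^2)
}

# closed-form lambda update: minimize a*lambda^2 + b*lambda over [0,1];
# when a = 0 (identical mixed orders) lambda keeps its previous value.
update_lambda <- function(state, Ls) {
  A1 <- mix_laplacian(Ls, state$mu, 1)
  A2 <- mix_laplacian(Ls, state$mu, 2)
  dL <- A1 - A2
  a <- sum(dL^2)
  if (a <= .Machine$double.eps) return(state$lambda)
  n <- nrow(A1)
  M <- diag(n) - state$W %*% (state$Lambda * t(state$W))
  b <- 2 * sum((A2 - M) * dL)   # both symmetric: elementwise trace
  min(max(-b / (2 * a), 0), 1)
}

# W update: smallest-c eigenvectors of B = Lf - HH'/2, assigned so that
# ascending eigenvalues pair with descending Lambda entries (the exact
# minimizer of tr(Lambda W' B W) over orthonormal W).
update_W_factor <- function(state, Ls) {
  Lf <- state$lambda * mix_laplacian(Ls, state$mu, 1) +
    (1 - state$lambda) * mix_laplacian(Ls, state$mu, 2)
  B <- Lf - 0.5 * tcrossprod(state$H)
  c <- ncol(state$W)
  V <- eig_smallest(B, c)$vectors
  W <- matrix(0, nrow(V), c)
  W[, order(state$Lambda, decreasing = TRUE)] <- V
  W
}

# Lambda update: coordinate-wise clamp of -C_ii to [0, 1]
update_Lambda <- function(state, Ls) {
  Lf <- state$lambda * mix_laplacian(Ls, state$mu, 1) +
    (1 - state$lambda) * mix_laplacian(Ls, state$mu, 2)
  Cd <- diag(crossprod(state$W, (Lf - 0.5 * tcrossprod(state$H)) %*% state$W)) - 1
  pmin(pmax(-Cd, 0), 1)
}

# H update: smallest-c eigenvectors of I - W Lambda W'
update_H <- function(state, Ls) {
  n <- nrow(state$W)
  M <- diag(n) - state$W %*% (state$Lambda * t(state$W))
  eig_smallest(M, ncol(state$W))$vectors
}

# mu update: simplex-constrained QP with Q_pq = tr(G_p G_q),
# f_p = 2 tr((W Lambda W' - I) G_p), G_p = lambda*L_p1 + (1-lambda)*L_p2
update_mu <- function(state, Ls) {
  V <- length(Ls)
  if (V == 1L) return(1)
  n <- nrow(state$W)
  G <- lapply(seq_len(V), function(p)
    state$lambda * Ls[[p]][[1]] + (1 - state$lambda) * Ls[[p]][[2]])
  Q <- matrix(0, V, V)
  for (p in seq_len(V)) for (q in p:V) {
    Q[p, q] <- Q[q, p] <- sum(G[[p]] * G[[q]])  # symmetric: tr(Gp Gq)
  }
  WL <- state$W %*% (state$Lambda * t(state$W)) - diag(n)
  f <- vapply(G, function(Gp) 2 * sum(WL * Gp), numeric(1))
  simplex_qp(Q, f)
}

#' Fuse a Laplacian stack and learn the common embedding
#'
#' Runs the alternating minimization of the fused-Laplacian objective:
#' order-mixing weight `lambda`, eigen-factor `W`, spectral weights
#' `Lambda`, embedding `H` and modality weights `mu` are updated cyclically,
#' each by its exact blockwise minimizer, until the relative objective
#' change falls below `tol`. Every step is verified to not increase the
#' objective (a violation beyond numerical tolerance signals a bug and
#' raises an error).
#'
#' Initialization is deterministic by default: `lambda = 1/2`, uniform
#' `mu`, `Lambda = I`, and `W = H =` the `c` smallest eigenvectors of the
#' uniformly averaged order-1 Laplacian. Stacks with a single order are
#' handled by replicating the order-1 Laplacian, which makes the order
#' mixing a no-op.
#'
#' @param stack a [laplacian_stack()].
#' @param c embedding dimension (number of columns of `H`), `1 <= c < n`.
#' @param max_iter maximum number of update cycles (default 100).
#' @param tol relative objective-change convergence tolerance (default 1e-6).
#' @param init `"spectral"` (deterministic, default) or `"random"`
#'   orthonormal starts for `W` and `H`.
#' @param seed integer seed used only by `init = "random"`.
#' @return object of class `"schoml_fusion"`: list with `H` (n x c
#'   embedding, rows named by cell), `lambda`, `mu`, `Lambda`, `W_factor`,
#'   `objective_trace`, `n_iter`, `converged`.
#' @export
fuse_laplacians <- function(stack, c, max_iter = 100, tol = 1e-6,
                            init = c("spectral", "random"), seed = NULL) {
  init <- match.arg(init)
  stopifnot(inherits(stack, "laplacian_stack"))
  n <- stack$n
  c <- as.integer(c)
  if (c < 1 || c >= n) stop("'c' must satisfy 1 <= c < n")
  if (tol <= 0) stop("'tol' must be positive")
  Ls <- stack$L
  if (stack$U == 1L) {
    Ls <- lapply(Ls, function(Lp) list(Lp[[1]], Lp[[1]]))
  } else if (stack$U > 2L) {
    Ls <- lapply(Ls, function(Lp) Lp[1:2])  # objective is written for two orders
  }
  V <- length(Ls)

  state <- list(lambda = 0.5, mu = rep(1 / V, V), Lambda = rep(1, c))
  if (init == "spectral") {
    Lavg <- mix_laplacian(Ls, rep(1 / V, V), 1)
    W0 <- eig_smallest(Lavg, c)$vectors
    state$W <- W0
    state$H <- W0
  } else {
    if (!is.null(seed)) set.seed(seed)
    state$W <- qr.Q(qr(matrix(stats::rnorm(n * c), n, c)))
    state$H <- qr.Q(qr(matrix(stats::rnorm(n * c), n, c)))
  }

  obj <- fusion_objective(state, Ls)
  trace <- obj
  check_step <- function(prev, cur, what) {
    if (cur > prev + 1e-9 * (1 + abs(prev)))
      stop(sprintf("objective increased during %s update (%.6g -> %.6g)",
                   what, prev, cur))
    cur
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    state$lambda <- update_lambda(state, Ls)
    obj <- check_step(obj, fusion_objective(state, Ls), "lambda")
    state$W <- update_W_factor(state, Ls)
    obj <- check_step(obj, fusion_objective(state, Ls), "W")
    state$Lambda <- update_Lambda(state, Ls)
    obj <- check_step(obj, fusion_objective(state, Ls), "Lambda")
    state$H <- update_H(state, Ls)
    obj <- check_step(obj, fusion_objective(state, Ls), "H")
    state$mu <- update_mu(state, Ls)
    obj <- check_step(obj, fusion_objective(state, Ls), "mu")
    prev <- trace[length(trace)]
    trace <- c(trace, obj)
    if (abs(prev - obj) < tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
  }
  if (!is.null(stack$cell_ids)) rownames(state$H) <- stack$cell_ids
  structure(list(H = state$H, lambda = state$lambda, mu = state$mu,
                 Lambda = state$Lambda, W_factor = state$W,
                 objective_trace = trace, n_iter = it,
                 converged = converged),
            class = "schoml_fusion")
}

#' @export
print.schoml_fusion <- function(x, ...) {
  cat(sprintf("Fused-Laplacian embedding: n = %d, c = %d\n",
              nrow(x$H), ncol(x$H)))
  cat(sprintf("  %d iteration(s), %sconverged; objective %.6g -> %.6g\n",
              x$n_iter, if (x$converged) "" else "NOT ",
              x$objective_trace[1], tail(x$objective_trace, 1)))
  cat("  lambda =", signif(x$lambda, 4),
      "; mu =", paste(signif(x$mu, 4), collapse = ", "), "\n")
  invisible(x)
}
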