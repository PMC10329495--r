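# Block factor-model simulators for paired two-modality single-cell data.
#
# Both generators draw X_m = (W_m + rho_f * E) %*% H, where W_m is a binary
# feature-block indicator (features x types), H a binary type indicator
# (types x cells) and E i.i.d. standard Gaussian factor noise shared by all
# cells of a type. Entries inside each feature block are then zeroed by
# Bernoulli dropout with block-level probability exp(-lambda * xbar^2),
# where xbar is the mean of the noise-free block of W_m %*% H (so an empty
# block, xbar = 0, is always dropped); finally i.i.d. Gaussian noise with
# the stated rho is added everywhere. Rows outside every block carry only
# factor and additive noise -- the factor-noise component, shared within a
# type, is what keeps types separable at high dropout.

dropout_probability <- function(xbar, lambda) exp(-lambda * xbar^2)

# features x cells draw for one modality; Wb: features x types indicator
simulate_modality <- function(Wb, Hb, rho_factor, rho_add, lambda,
                              dropout = TRUE) {
  d <- nrow(Wb)
  n <- ncol(Hb)
  X0 <- Wb %*% Hb                      # noise-free ground truth
  W <- Wb + rho_factor * matrix(stats::rnorm(length(Wb)), d)
  X <- W %*% Hb
  if (dropout) {
    for (j in seq_len(ncol(Wb))) {
      rows <- which(Wb[, j] > 0)
      if (!length(rows)) next
      p <- dropout_probability(mean(X0[rows, ]), lambda)
      keep <- matrix(stats::rbinom(length(rows) * n, 1, 1 - p), length(rows), n)
      X[rows, ] <- X[rows, ] * keep
    }
  }
  if (rho_add > 0)
    X <- X + rho_add * matrix(stats::rnorm(length(X)), d)
  X
}

finish_dataset <- function(X1, X2, labels, provenance) {
  n <- ncol(X1)
  ids <- auto_ids(n)
  X1 <- t(X1); X2 <- t(X2)             # cells x features
  rownames(X1) <- rownames(X2) <- ids
  colnames(X1) <- auto_ids(ncol(X1), "m1_feat")
  colnames(X2) <- auto_ids(ncol(X2), "m2_feat")
  names(labels) <- ids
  structure(list(X1 = X1, X2 = X2, labels = labels,
                 provenance = provenance),
            class = "schoml_sim")
}

#' Simulate paired-modality dataset 1 (three cell types, noise grid)
#'
#' 200 cells in three types (70/60/70), modality 1 with 5000 features and
#' modality 2 with 2000. Feature blocks: modality 1 rows 1-100, 151-300,
#' 501-800 mark the three types; modality 2 rows 1-500 and 1001-1500 mark
#' types 1-2 (the third block of the published construction falls outside
#' the 2000 features, so type 3's modality-2 signature is the zero
#' pattern). Factor noise at `rho_factor`, block-level Bernoulli dropout
#' at rates `lambda1`/`lambda2`, then additive Gaussian noise at
#' `rho1`/`rho2` -- the two levels that form the benchmark noise grid.
#'
#' @param rho1,rho2 additive noise levels for modalities 1 and 2
#'   (grid defaults: `rho1` in 3..5 by 0.5, `rho2` in 0.2..1 by 0.2).
#' @param rho_factor factor-noise level (default 0.5).
#' @param lambda1,lambda2 dropout decay rates (defaults 0.05 / 0.025).
#' @param dropout apply dropout? `FALSE` gives the dropout-free limit.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return object of class `"schoml_sim"`: list with `X1` (200 x 5000),
#'   `X2` (200 x 2000), `labels` (length 200) and `provenance`.
#' @export
simulate_dataset1 <- function(rho1 = 3, rho2 = 0.2, rho_factor = 0.5,
                              lambda1 = 0.05, lambda2 = 0.025,
                              dropout = TRUE, seed = NULL) {
  stopifnot(rho1 >= 0, rho2 >= 0, rho_factor >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- 200L
  W1 <- matrix(0, 5000, 3)
  W1[1:100, 1] <- 1; W1[151:300, 2] <- 1; W1[501:800, 3] <- 1
  W2 <- matrix(0, 2000, 3)
  W2[1:500, 1] <- 1; W2[1001:1500, 2] <- 1   # third block out of range
  Hb <- matrix(0, 3, n)
  Hb[1, 1:70] <- 1; Hb[2, 71:130] <- 1; Hb[3, 131:200] <- 1
  labels <- rep(1:3, c(70, 60, 70))
  X1 <- simulate_modality(W1, Hb, rho_factor, rho1, lambda1, dropout)
  X2 <- simulate_modality(W2, Hb, rho_factor, rho2, lambda2, dropout)
  finish_dataset(X1, X2, labels,
                 list(dataset = 1L, rho1 = rho1, rho2 = rho2,
                      rho_factor = rho_factor, lambda1 = lambda1,
                      lambda2 = lambda2, dropout = dropout, seed = seed))
}

#' Simulate paired-modality dataset 2 (epigenetic sub-structure)
#'
#' 500 cells, modality 1 with 5000 features and modality 2 with 2000,
#' emulating the setting where clusters defined by the epigenetic modality
#' do not all have transcriptomic counterparts. Modality 2 has `K2`
#' consecutive 500-row feature blocks (one per epigenetic group; blocks
#' beyond the 2000 features are empty); modality 1 has 200-row blocks for
#' the first three groups only, with groups 3..K2 sharing the third block,
#' so its rank stays 3. Cells split into `K2` consecutive groups of
#' `500 / K2` (the last absorbs the remainder). After factor noise,
#' dropout and additive noise, modality 2 is binarized at
#' `binarize_threshold`. Ground-truth labels are the four
#' transcriptome-level types (125 cells each) of the default `K2 = 4`
#' configuration.
#'
#' @param K2 number of epigenetic groups / rank of the modality-2 factor,
#'   between 3 and 7 (default 4).
#' @param rho1,rho2 additive noise levels (defaults 2 / 1).
#' @param rho_factor factor-noise level (default 0.5).
#' @param lambda1,lambda2 dropout decay rates (defaults 0.05 / 0.025).
#' @param binarize_threshold modality-2 binarization cutoff (default 0.7);
#'   `NA` skips binarization.
#' @param dropout apply dropout? `FALSE` gives the dropout-free limit.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return object of class `"schoml_sim"` as in [simulate_dataset1()];
#'   `X2` is binary.
#' @export
simulate_dataset2 <- function(K2 = 4, rho1 = 2, rho2 = 1, rho_factor = 0.5,
                              lambda1 = 0.05, lambda2 = 0.025,
                              binarize_threshold = 0.7,
                              dropout = TRUE, seed = NULL) {
  K2 <- as.integer(K2)
  if (K2 < 3 || K2 > 7) stop("'K2' must be between 3 and 7")
  stopifnot(rho1 >= 0, rho2 >= 0, rho_factor >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- 500L
  W1 <- matrix(0, 5000, K2)
  for (j in seq_len(K2)) {             # groups >= 3 share block 3: rank 3
    b <- min(j, 3L)
    W1[((b - 1) * 200 + 1):(b * 200), j] <- 1
  }
  W2 <- matrix(0, 2000, K2)
  for (j in seq_len(K2)) {
    lo <- (j - 1) * 500 + 1
    if (lo <= 2000) W2[lo:min(j * 500, 2000), j] <- 1
  }
  sizes <- rep(n %/% K2, K2)
  sizes[K2] <- n - sum(sizes[-K2])
  Hb <- matrix(0, K2, n)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  for (j in seq_len(K2)) Hb[j, starts[j]:ends[j]] <- 1
  labels <- rep(1:4, each = 125)
  X1 <- simulate_modality(W1, Hb, rho_factor, rho1, lambda1, dropout)
  X2 <- simulate_modality(W2, Hb, rho_factor, rho2, lambda2, dropout)
  if (!is.na(binarize_threshold)) X2 <- (X2 > binarize_threshold) * 1
  finish_dataset(X1, X2, labels,
                 list(dataset = 2L, K2 = K2, rho1 = rho1, rho2 = rho2,
                      rho_factor = rho_factor, lambda1 = lambda1,
                      lambda2 = lambda2,
                      binarize_threshold = binarize_threshold,
                      dropout = dropout, seed = seed))
}

#' @export
print.schoml_sim <- function(x, ...) {
  cat(sprintf("Simulated paired dataset %d: %d cells, %d + %d features, %d types\n",
              x$provenance$dataset, nrow(x$X1), ncol(x$X1), ncol(x$X2),
              length(unique(x$labels))))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Writes `X1`, `X2` (CSV or MatrixMarket with name sidecars),
#' `labels.csv` (`cell_id,label`) and `provenance.yaml` (generator
#' parameters including the seed). [read_dataset()] inverts it.
#'
#' @param ds a `"schoml_sim"` object.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "schoml_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "mtx") "mtx" else "csv"
  write_modality(ds$X1, file.path(dir, paste0("X1.", ext)), format)
  write_modality(ds$X2, file.path(dir, paste0("X2.", ext)), format)
  data.table::fwrite(data.frame(cell_id = names(ds$labels),
                                label = unname(ds$labels)),
                     file.path(dir, "labels.csv"))
  prov <- ds$provenance
  prov$format <- format
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir directory containing `X1.*`, `X2.*`, `labels.csv`,
#'   `provenance.yaml`.
#' @return object of class `"schoml_sim"`.
#' @export
read_dataset <- function(dir) {
  prov <- yaml::read_yaml(file.path(dir, "provenance.yaml"))
  ext <- if (identical(prov$format, "mtx")) "mtx" else "csv"
  X1 <- read_modality(file.path(dir, paste0("X1.", ext)))
  X2 <- read_modality(file.path(dir, paste0("X2.", ext)))
  lab <- data.table::fread(file.path(dir, "labels.csv"), data.table = FALSE)
  labels <- lab$label
  names(labels) <- lab$cell_id
  prov$format <- NULL
  structure(list(X1 = X1, X2 = X2, labels = labels, provenance = prov),
            class = "schoml_sim")
}
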