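#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions
#' (up to relabeling), expected value 0 under independent random
#' labelings.
#'
#' @param truth,predicted label vectors of equal length (any atomic type).
#' @return a number `<= 1`.
#' @export
ari <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("label vectors differ in length")
  if (length(truth) == 0) stop("empty label vectors")
  mclust::adjustedRandIndex(truth, predicted)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the two labelings normalized by their entropies;
#' 1 for identical partitions, 0 when one labeling carries no information
#' about the other. The normalization denominator is the arithmetic mean
#' of the two entropies by default, with geometric-mean, min and max
#' variants available.
#'
#' @param truth,predicted label vectors of equal length.
#' @param normalization entropy normalization variant.
#' @return a number in \[0, 1\].
#' @export
nmi <- function(truth, predicted,
                normalization = c("arithmetic", "geometric", "min", "max")) {
  normalization <- match.arg(normalization)
  if (length(truth) != length(predicted))
    stop("label vectors differ in length")
  n <- length(truth)
  if (n == 0) stop("empty label vectors")
  tab <- table(truth, predicted)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  H1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  H2 <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (H1 == 0 && H2 == 0) return(1)  # both single-cluster: identical
  denom <- switch(normalization,
                  arithmetic = (H1 + H2) / 2,
                  geometric = sqrt(H1 * H2),
                  min = min(H1, H2),
                  max = max(H1, H2))
  if (denom == 0) return(0)
  max(0, min(1, I / denom))
}
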