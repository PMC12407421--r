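# Maximum mean discrepancy between feature batches, with a Gaussian
# multi-bandwidth kernel. Used as an auxiliary training loss aligning the
# flattened features of the synthetic and photograph domains, and exposed
# directly as a two-sample statistic.

#' MMD loss configuration
#'
#' @param bandwidths Positive kernel bandwidths, or `NULL` for the median
#'   heuristic (median pairwise distance of the pooled batch) scaled by
#'   `bandwidth_multipliers`.
#' @param bandwidth_multipliers Multipliers applied to the median-heuristic
#'   bandwidth.
#' @param estimator `"biased"` (V-statistic, always >= 0) or `"unbiased"`
#'   (U-statistic, excludes the within-batch diagonals).
#' @param lambda Non-negative weight of the MMD^2 term in the training loss.
#' @return An `mmd_config` object.
#' @export
mmd_config <- function(bandwidths = NULL,
                       bandwidth_multipliers = c(0.5, 1, 2),
                       estimator = c("biased", "unbiased"), lambda = 1) {
  estimator <- match.arg(estimator)
  if (!is.null(bandwidths)) {
    assert_that(all(bandwidths > 0), "bandwidths must be positive")
  }
  assert_that(lambda >= 0, "lambda must be non-negative")
  structure(list(bandwidths = bandwidths,
                 bandwidth_multipliers = bandwidth_multipliers,
                 estimator = estimator, lambda = lambda),
            class = "mmd_config")
}

# Median-heuristic bandwidth of the pooled batch.
median_bandwidth <- function(A, B) {
  X <- rbind(A, B)
  d <- as.vector(stats::dist(X))
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

sq_dists <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Gaussian kernel matrix summed over bandwidths
#'
#' Entry (i, j) is `sum_b exp(-||a_i - b_j||^2 / (2 b^2))`, so it equals the
#' number of bandwidths when `a_i == b_j` and is symmetric when `A == B`.
#'
#' @param A,B Feature batches (rows = samples) of equal width.
#' @param bandwidths Positive bandwidths.
#' @return `nrow(A) x nrow(B)` kernel matrix.
#' @export
gaussian_kernel_matrix <- function(A, B, bandwidths = 1) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  assert_that(ncol(A) == ncol(B), "feature widths must match")
  assert_that(all(bandwidths > 0), "bandwidths must be positive")
  d2 <- sq_dists(A, B)
  K <- matrix(0, nrow(A), nrow(B))
  for (bw in bandwidths) K <- K + exp(-d2 / (2 * bw^2))
  K
}

#' Squared maximum mean discrepancy between two batches
#'
#' The biased (V-statistic) estimator is
#' `mean(K_AA) + mean(K_BB) - 2 mean(K_AB)`; it is non-negative and exactly
#' zero when the batches are identical as multisets. The unbiased estimator
#' excludes the diagonals of the within-batch kernel matrices and can be
#' negative under the null.
#'
#' @param A,B Feature batches of equal width.
#' @param cfg An [mmd_config()].
#' @return Scalar MMD^2 estimate.
#' @export
mmd2 <- function(A, B, cfg = mmd_config()) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  assert_that(ncol(A) == ncol(B), "feature widths must match")
  m <- nrow(A)
  n <- nrow(B)
  if (cfg$estimator == "unbiased") {
    assert_that(m >= 2 && n >= 2,
                "the unbiased estimator needs at least 2 rows per batch")
  } else {
    assert_that(m >= 1 && n >= 1, "batches must be nonempty")
  }
  bw <- cfg$bandwidths %||%
    (median_bandwidth(A, B) * cfg$bandwidth_multipliers)
  KAA <- gaussian_kernel_matrix(A, A, bw)
  KBB <- gaussian_kernel_matrix(B, B, bw)
  KAB <- gaussian_kernel_matrix(A, B, bw)
  if (cfg$estimator == "biased") {
    mean(KAA) + mean(KBB) - 2 * mean(KAB)
  } else {
    (sum(KAA) - sum(diag(KAA))) / (m * (m - 1)) +
      (sum(KBB) - sum(diag(KBB))) / (n * (n - 1)) -
      2 * mean(KAB)
  }
}

# Biased MMD^2 with gradients w.r.t. both batches, for training. For one
# bandwidth, d k(a_i, b_j) / d a_i = k(a_i, b_j) (b_j - a_i) / bw^2; the
# within- and cross-term contributions are accumulated over bandwidths.
mmd2_with_grad <- function(A, B, bandwidths) {
  m <- nrow(A)
  n <- nrow(B)
  d2_AA <- sq_dists(A, A)
  d2_BB <- sq_dists(B, B)
  d2_AB <- sq_dists(A, B)
  val <- 0
  dA <- A * 0
  dB <- B * 0
  for (bw in bandwidths) {
    KAA <- exp(-d2_AA / (2 * bw^2))
    KBB <- exp(-d2_BB / (2 * bw^2))
    KAB <- exp(-d2_AB / (2 * bw^2))
    val <- val + mean(KAA) + mean(KBB) - 2 * mean(KAB)
    # within-A term: (2 / m^2) sum_j K_ij (a_j - a_i) / bw^2
    dA <- dA + (2 / (m^2 * bw^2)) * (KAA %*% A - rowSums(KAA) * A)
    dB <- dB + (2 / (n^2 * bw^2)) * (KBB %*% B - rowSums(KBB) * B)
    # cross term: -(2 / mn) * 2-sided
    dA <- dA - (2 / (m * n * bw^2)) * (KAB %*% B - rowSums(KAB) * A)
    dB <- dB - (2 / (m * n * bw^2)) * (t(KAB) %*% A - colSums(KAB) * B)
  }
  list(value = val, dA = dA, dB = dB)
}
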