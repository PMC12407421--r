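# Exact (O(N^2)) t-SNE, sufficient for the few hundred test images embedded
# by the evaluation suite. Deterministic given the seed.

# Conditional probabilities with per-point precision tuned by bisection to
# match the target perplexity.
tsne_input_probs <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf
    hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:60) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s <= 0) {
        h <- 0
        p <- p * 0
      } else {
        p <- p / s
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-6) break
      if (h > target) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Core t-SNE on a feature matrix. Internal; see embed_tsne() for the
# user-facing operation that carries labels and domain tags through.
tsne_embed <- function(X, perplexity = 30, seed = 1, n_iter = 400,
                       eta = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  assert_that(perplexity >= 2, "too few points for t-SNE")
  # PCA compression, the conventional preprocessing for wide feature matrices
  k <- min(50, ncol(X), n - 1)
  if (ncol(X) > k) {
    X <- stats::prcomp(X, rank. = k, center = TRUE, scale. = FALSE)$x
  }
  P <- tsne_input_probs(as.matrix(stats::dist(X))^2, perplexity)

  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  exagg <- 12
  for (it in seq_len(n_iter)) {
    Pn <- if (it <= 100) P * exagg else P
    d2 <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + d2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pn - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
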