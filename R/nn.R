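# A small convolutional classifier with hand-written forward/backward passes.
#
# Layout (shared by every backbone kind): a stack of 3x3 same-padding conv +
# ReLU stages with 2x2 max pooling between stages, then the classification
# head: max pooling -> flatten -> dense (ReLU) -> dense -> softmax. Two taps
# are exposed for analysis: the flattened post-convolution features (used by
# the MMD loss and the t-SNE embeddings) and the final convolutional
# activations (used by Grad-CAM).
#
# Images are H x W x 3 x N arrays with values in [0, 1].

#' Backbone configuration
#'
#' @param kind `"tiny"` (two conv stages, 8 and 16 channels) or
#'   `"vgg19_like"` (the 16-conv-layer VGG19 feature stack).
#' @param pretrained Load externally supplied weights (`vgg19_like` only);
#'   no weights ship with the package, so this requires `weights_path`.
#' @param weights_path Optional RDS file holding a compatible parameter list.
#' @param head_hidden Width of the hidden dense layer.
#' @return A `backbone_config` object.
#' @export
backbone_config <- function(kind = c("tiny", "vgg19_like"),
                            pretrained = FALSE, weights_path = NULL,
                            head_hidden = 64) {
  kind <- match.arg(kind)
  if (pretrained && kind != "vgg19_like") {
    stop_argument("pretrained weights are only defined for the vgg19_like backbone")
  }
  if (pretrained && is.null(weights_path)) {
    stop_argument("no pretrained weights are bundled; supply weights_path")
  }
  stages <- switch(kind,
    tiny = list(8L, 16L),
    vgg19_like = list(c(64L, 64L), c(128L, 128L),
                      c(256L, 256L, 256L, 256L),
                      c(512L, 512L, 512L, 512L),
                      c(512L, 512L, 512L, 512L))
  )
  structure(list(kind = kind, stages = stages, pretrained = pretrained,
                 weights_path = weights_path, head_hidden = head_hidden),
            class = "backbone_config")
}

#' Build an (untrained) classifier
#'
#' @param cfg A [backbone_config()].
#' @param n_classes Number of output classes (>= 2).
#' @param input_side Input image side in pixels; must be divisible by
#'   2^(number of pooling layers).
#' @param seed Seed for He-normal weight initialisation.
#' @return An `ma_model` with fields `params`, `feature_dim`, `n_classes`.
#' @export
build_classifier <- function(cfg, n_classes, input_side = 32, seed = 1) {
  assert_that(inherits(cfg, "backbone_config"), "cfg must be a backbone_config")
  assert_that(n_classes >= 2, "n_classes must be at least 2")
  n_pools <- length(cfg$stages)  # pools between stages + head pool
  assert_that(input_side %% (2^n_pools) == 0,
              "input_side must be divisible by 2^", n_pools)
  widths <- unlist(cfg$stages)
  stage_of <- rep(seq_along(cfg$stages), lengths(cfg$stages))
  side <- input_side
  in_ch <- 3L
  conv <- list()
  with_seed(seed, {
    for (l in seq_along(widths)) {
      fan_in <- 9L * in_ch
      conv[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * widths[l]) * sqrt(2 / fan_in),
                   fan_in, widths[l]),
        b = rep(0, widths[l])
      )
      in_ch <- widths[l]
      if (l < length(widths) && stage_of[l + 1] != stage_of[l]) side <- side / 2
    }
    conv_side <- side          # spatial side of the final conv activations
    feat_side <- side / 2      # after the head max pool
    feature_dim <- as.integer(feat_side^2 * in_ch)
    fc1 <- list(W = matrix(stats::rnorm(feature_dim * cfg$head_hidden) *
                             sqrt(2 / feature_dim),
                           feature_dim, cfg$head_hidden),
                b = rep(0, cfg$head_hidden))
    fc2 <- list(W = matrix(stats::rnorm(cfg$head_hidden * n_classes) *
                             sqrt(1 / cfg$head_hidden),
                           cfg$head_hidden, n_classes),
                b = rep(0, n_classes))
    model <- structure(list(
      backbone = cfg, n_classes = as.integer(n_classes),
      input_side = as.integer(input_side),
      stage_of = stage_of, widths = widths,
      conv_side = as.integer(conv_side), feature_dim = feature_dim,
      params = list(conv = conv, fc1 = fc1, fc2 = fc2)
    ), class = "ma_model")
    if (cfg$pretrained) {
      model$params <- readRDS(cfg$weights_path)
    }
    model
  })
}

# ---- layer primitives -------------------------------------------------------

# im2col gather indices for a 3x3 same-padding convolution.
conv_indices <- function(H, W, C, N) {
  Hp <- H + 2L
  Wp <- W + 2L
  i_idx <- rep(seq_len(H), W)
  j_idx <- rep(seq_len(W), each = H)
  base <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    base[, k] <- (j_idx - 1L + dj) * Hp + (i_idx + di)
  }
  list(base = base, Hp = Hp, Wp = Wp,
       n_off = rep((seq_len(N) - 1L) * Hp * Wp * C, each = H * W))
}

conv_forward <- function(X, layer, idx = NULL) {
  d <- dim(X)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (is.null(idx)) idx <- conv_indices(H, W, C, N)
  Xp <- array(0, dim = c(idx$Hp, idx$Wp, C, N))
  Xp[2:(H + 1), 2:(W + 1), , ] <- X
  xf <- as.vector(Xp)
  cols <- matrix(0, H * W * N, 9L * C)
  HpWp <- idx$Hp * idx$Wp
  for (c in seq_len(C)) {
    coff <- (c - 1L) * HpWp
    for (k in 1:9) {
      cols[, (c - 1L) * 9L + k] <- xf[rep(idx$base[, k], N) + coff + idx$n_off]
    }
  }
  Y <- cols %*% layer$W
  Y <- sweep(Y, 2, layer$b, "+")
  Cout <- ncol(layer$W)
  Y4 <- aperm(array(Y, dim = c(H, W, N, Cout)), c(1, 2, 4, 3))
  list(out = Y4, cols = cols, idx = idx, dims = c(H, W, C, N, Cout))
}

conv_backward <- function(fw, layer, dY) {
  d <- fw$dims
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; Cout <- d[5]
  dYmat <- matrix(aperm(dY, c(1, 2, 4, 3)), H * W * N, Cout)
  dW <- crossprod(fw$cols, dYmat)
  db <- colSums(dYmat)
  dcols <- tcrossprod(dYmat, layer$W)
  idx <- fw$idx
  HpWp <- idx$Hp * idx$Wp
  dXp <- numeric(HpWp * C * N)
  for (c in seq_len(C)) {
    coff <- (c - 1L) * HpWp
    for (k in 1:9) {
      at <- rep(idx$base[, k], N) + coff + idx$n_off
      dXp[at] <- dXp[at] + dcols[, (c - 1L) * 9L + k]
    }
  }
  dXp <- array(dXp, dim = c(idx$Hp, idx$Wp, C, N))
  list(dX = dXp[2:(H + 1), 2:(W + 1), , , drop = FALSE], dW = dW, db = db)
}

pool_forward <- function(X) {
  d <- dim(X)
  ro <- seq(1, d[1], by = 2)
  co <- seq(1, d[2], by = 2)
  s1 <- X[ro, co, , , drop = FALSE]
  s2 <- X[ro + 1, co, , , drop = FALSE]
  s3 <- X[ro, co + 1, , , drop = FALSE]
  s4 <- X[ro + 1, co + 1, , , drop = FALSE]
  out <- pmax(s1, s2, s3, s4)
  arg <- 1L * (s1 == out)
  arg[arg == 0 & s2 == out] <- 2L
  arg[arg == 0 & s3 == out] <- 3L
  arg[arg == 0 & s4 == out] <- 4L
  list(out = out, arg = arg, in_dim = d)
}

pool_backward <- function(fw, dY) {
  d <- fw$in_dim
  dX <- array(0, dim = d)
  ro <- seq(1, d[1], by = 2)
  co <- seq(1, d[2], by = 2)
  dX[ro, co, , ] <- dY * (fw$arg == 1L)
  dX[ro + 1, co, , ] <- dY * (fw$arg == 2L)
  dX[ro, co + 1, , ] <- dY * (fw$arg == 3L)
  dX[ro + 1, co + 1, , ] <- dY * (fw$arg == 4L)
  dX
}

softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Forward pass of a classifier
#'
#' @param model An `ma_model`.
#' @param X Image batch, `H x W x 3 x N` array in `[0, 1]`.
#' @param want_cache Keep intermediate activations for a backward pass.
#' @return List with `logits` and `probs` (`N x C`), `feats` (`N x
#'   feature_dim`, the flattened post-convolution tap), `conv_final`
#'   (final conv activations, post-ReLU) and, optionally, `cache`.
#' @export
model_forward <- function(model, X, want_cache = FALSE) {
  if (length(dim(X)) == 3) dim(X) <- c(dim(X), 1L)
  stage_of <- model$stage_of
  conv_fw <- list()
  pool_fw <- list()
  relu_mask <- list()
  A <- X
  for (l in seq_along(model$widths)) {
    fw <- conv_forward(A, model$params$conv[[l]])
    A <- fw$out
    mask <- A > 0
    A <- A * mask
    if (want_cache) {
      conv_fw[[l]] <- fw[c("cols", "idx", "dims")]
      relu_mask[[l]] <- mask
    }
    if (l < length(model$widths) && stage_of[l + 1] != stage_of[l]) {
      pf <- pool_forward(A)
      A <- pf$out
      if (want_cache) pool_fw[[l]] <- pf[c("arg", "in_dim")]
    }
  }
  conv_final <- A
  head_pool <- pool_forward(A)
  P <- head_pool$out
  dP <- dim(P)
  N <- dP[4]
  feats <- t(matrix(P, prod(dP[1:3]), N))  # N x feature_dim
  Z1 <- sweep(feats %*% model$params$fc1$W, 2, model$params$fc1$b, "+")
  H1 <- Z1 * (Z1 > 0)
  logits <- sweep(H1 %*% model$params$fc2$W, 2, model$params$fc2$b, "+")
  out <- list(logits = logits, probs = softmax(logits), feats = feats,
              conv_final = conv_final)
  if (want_cache) {
    out$cache <- list(conv = conv_fw, pool = pool_fw, relu = relu_mask,
                      head_pool = head_pool[c("arg", "in_dim")],
                      feats = feats, Z1 = Z1, H1 = H1, feat_dim3 = dP[1:3])
  }
  out
}

# Backward pass from logits (and optionally extra gradient injected at the
# feature tap, as the MMD loss does). Returns grads matching model$params.
model_backward <- function(model, fwd, dlogits, dfeats_extra = NULL) {
  cache <- fwd$cache
  g <- list(conv = vector("list", length(model$widths)))
  g$fc2 <- list(W = crossprod(cache$H1, dlogits), b = colSums(dlogits))
  dH1 <- tcrossprod(dlogits, model$params$fc2$W)
  dZ1 <- dH1 * (cache$Z1 > 0)
  g$fc1 <- list(W = crossprod(cache$feats, dZ1), b = colSums(dZ1))
  dfeats <- tcrossprod(dZ1, model$params$fc1$W)
  if (!is.null(dfeats_extra)) dfeats <- dfeats + dfeats_extra
  N <- nrow(dfeats)
  dP <- array(t(dfeats), dim = c(cache$feat_dim3, N))
  dA <- pool_backward(cache$head_pool, dP)
  stage_of <- model$stage_of
  for (l in rev(seq_along(model$widths))) {
    dA <- dA * cache$relu[[l]]
    bw <- conv_backward(cache$conv[[l]], model$params$conv[[l]], dA)
    g$conv[[l]] <- list(W = bw$dW, b = bw$db)
    dA <- bw$dX
    if (l > 1 && stage_of[l - 1] != stage_of[l]) {
      dA <- pool_backward(cache$pool[[l - 1]], dA)
    }
  }
  g[c("conv", "fc1", "fc2")]  # match the layout of model$params
}

# Gradient of selected logits w.r.t. the final conv activations, through the
# head only (used by Grad-CAM). `class_idx` is one target class per sample.
grad_wrt_conv_final <- function(model, fwd, class_idx) {
  cache <- fwd$cache
  N <- nrow(fwd$logits)
  dlogits <- matrix(0, N, model$n_classes)
  dlogits[cbind(seq_len(N), class_idx)] <- 1
  dH1 <- tcrossprod(dlogits, model$params$fc2$W)
  dZ1 <- dH1 * (cache$Z1 > 0)
  dfeats <- tcrossprod(dZ1, model$params$fc1$W)
  dP <- array(t(dfeats), dim = c(cache$feat_dim3, N))
  pool_backward(cache$head_pool, dP)
}

# Cross-entropy loss and logit gradient for integer labels (1-based).
cross_entropy <- function(probs, y) {
  n <- nrow(probs)
  p <- pmax(probs[cbind(seq_len(n), y)], 1e-12)
  loss <- -mean(log(p))
  dlogits <- probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n)
}

# ---- Adam optimiser ---------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.list(p)) adam_init(p) else list(m = p * 0, v = p * 0)
  })
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (!is.list(p)) {
      return(upd(p, g, s))
    }
    out_p <- p
    out_s <- s
    for (nm in seq_along(p)) {
      r <- walk(p[[nm]], g[[nm]], s[[nm]])
      out_p[[nm]] <- r$p
      out_s[[nm]] <- r$s
    }
    list(p = out_p, s = out_s)
  }
  walk(params, grads, state)
}
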