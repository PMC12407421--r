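# evalsuite: accuracy/confusion reporting, t-SNE silhouette domain-confusion
# analysis, Grad-CAM heatmaps and automated focus scoring.

#' Classification accuracy on a dataset
#'
#' Fraction of records whose argmax class probability matches the label;
#' probability ties break toward the lowest class index.
#'
#' @param model A `trained_model`.
#' @param data A dataset (see [as_image_dataset()]).
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, data) {
  assert_that(dataset_size(data) > 0, "dataset must be nonempty")
  probs <- predict(model, data)
  mean(max.col(probs, ties.method = "first") == data$y)
}

#' Row-normalised confusion matrix
#'
#' Rows index the true class, columns the predicted class; every row with at
#' least one record is normalised to sum to one, empty rows stay all-zero.
#'
#' @inheritParams evaluate_accuracy
#' @return `C x C` matrix with class labels as dimnames.
#' @export
confusion_matrix <- function(model, data) {
  assert_that(dataset_size(data) > 0, "dataset must be nonempty")
  probs <- predict(model, data)
  pred <- max.col(probs, ties.method = "first")
  C <- length(data$classes)
  cm <- matrix(0, C, C, dimnames = list(true = data$classes,
                                        predicted = data$classes))
  for (i in seq_along(pred)) cm[data$y[i], pred[i]] <- cm[data$y[i], pred[i]] + 1
  rs <- rowSums(cm)
  cm[rs > 0, ] <- cm[rs > 0, , drop = FALSE] / rs[rs > 0]
  cm
}

#' Embed features in 2-D with t-SNE
#'
#' Embeds the flattened post-convolution features (or any feature matrix) and
#' carries species labels and domain tags through for downstream silhouette
#' analysis.
#'
#' @param features `N x D` matrix.
#' @param labels Species label per row.
#' @param domains Domain tag per row (`"synthetic"` / `"photo"`).
#' @param seed Integer seed; the embedding is deterministic given it.
#' @param perplexity t-SNE perplexity (reduced automatically for small N).
#' @return An `embedding2d`: `list(points, labels, domains, seed)`.
#' @export
embed_tsne <- function(features, labels, domains, seed = 1, perplexity = 30) {
  features <- as.matrix(features)
  assert_that(nrow(features) >= 5, "need at least 5 points to embed")
  assert_that(length(labels) == nrow(features) &&
                length(domains) == nrow(features),
              "labels and domains must match the feature rows")
  pts <- tsne_embed(features, perplexity = perplexity, seed = seed)
  structure(list(points = pts, labels = as.character(labels),
                 domains = as.character(domains), seed = as.integer(seed)),
            class = "embedding2d")
}

# Mean silhouette width of a labelled point set (Euclidean), via cluster::.
mean_silhouette <- function(points, labels) {
  labs <- as.integer(factor(labels))
  if (length(unique(labs)) < 2) {
    stop("undefined silhouette: subset has a single label")
  }
  sil <- cluster::silhouette(labs, stats::dist(points))
  mean(sil[, "sil_width"])
}

#' Per-domain and combined silhouette scores of an embedding
#'
#' Clusters are the ground-truth species labels; scores are mean silhouette
#' widths on the 2-D embedding (Euclidean), computed on the synthetic-only
#' subset, the photo-only subset, and both pooled.
#'
#' @param emb An `embedding2d` from [embed_tsne()].
#' @return Named numeric vector `c(synthetic =, photo =, combined =)`.
#' @export
silhouette_scores <- function(emb) {
  assert_that(inherits(emb, "embedding2d"), "emb must be an embedding2d")
  syn <- emb$domains == "synthetic"
  pho <- emb$domains == "photo"
  c(synthetic = mean_silhouette(emb$points[syn, , drop = FALSE],
                                emb$labels[syn]),
    photo = mean_silhouette(emb$points[pho, , drop = FALSE],
                            emb$labels[pho]),
    combined = mean_silhouette(emb$points, emb$labels))
}

# Bilinear upsampling of a matrix to side x side (same half-pixel mapping as
# resize()).
upsample_bilinear <- function(m, side) {
  if (nrow(m) == side && ncol(m) == side) return(m)
  rec <- image_record(array(rep(m, 3), dim = c(dim(m), 3)),
                      matrix(FALSE, nrow(m), ncol(m)))
  resize(rec, side)$pixels[, , 1]
}

#' Grad-CAM heatmap for one image
#'
#' Channel weights are the spatial averages of the gradients of the target
#' class's logit with respect to the final convolutional activations; the map
#' is the rectified weighted sum of those activation channels, bilinearly
#' upsampled to the image size and max-normalised to `[0, 1]` (an all-zero
#' map stays all-zero).
#'
#' @param model A `trained_model`.
#' @param img An `image_record` or an `H x W x 3` array.
#' @param target_class Class index; defaults to the predicted class.
#' @return `H x W` heatmap in `[0, 1]`.
#' @export
gradcam <- function(model, img, target_class = NULL) {
  x <- if (inherits(img, "image_record")) img$pixels else img
  side <- dim(x)[1]
  dim(x) <- c(dim(x), 1L)
  fwd <- model_forward(model$model, x, want_cache = TRUE)
  cls <- target_class %||% max.col(fwd$probs, ties.method = "first")
  dconv <- grad_wrt_conv_final(model$model, fwd, cls)
  A <- fwd$conv_final[, , , 1]
  G <- dconv[, , , 1]
  w <- apply(G, 3, mean)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (ch in seq_along(w)) cam <- cam + w[ch] * A[, , ch]
  cam <- pmax(cam, 0)
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  upsample_bilinear(cam, side)
}

#' Score a Grad-CAM heatmap against the foreground mask
#'
#' Let `f` be the fraction of heatmap mass above 50% of the map maximum that
#' falls inside the foreground mask. The score is 3 if `f >= 0.9`, 2 if
#' `f >= 0.6`, 1 if `f >= 0.3`, else 0 (thresholds configurable). High scores
#' mean the classifier focuses on the specimen rather than the background.
#'
#' @param heatmap `H x W` map in `[0, 1]`.
#' @param foreground_mask `H x W` logical mask.
#' @param thresholds Increasing cut points for scores 1, 2, 3.
#' @param hot_cut Fraction of the map maximum defining "hot" pixels.
#' @return Integer score in `{0, 1, 2, 3}`.
#' @export
gradcam_score <- function(heatmap, foreground_mask,
                          thresholds = c(0.3, 0.6, 0.9), hot_cut = 0.5) {
  assert_that(all(dim(heatmap) == dim(foreground_mask)),
              "heatmap and mask shapes must match")
  mx <- max(heatmap)
  if (mx <= 0) return(0L)
  hot <- heatmap >= hot_cut * mx
  total <- sum(heatmap[hot])
  if (total <= 0) return(0L)
  f <- sum(heatmap[hot & foreground_mask]) / total
  sum(f >= thresholds)
}

#' Grad-CAM focus scores over a record sample
#'
#' Draws a seeded sample without replacement, scores each image's Grad-CAM
#' against its foreground mask, and reports the score histogram and mean
#' (e.g. a model with 96 images at 3 and four at 2 averages 2.96).
#'
#' @param model A `trained_model`.
#' @param data A dataset (see [as_image_dataset()]); its `mask` slot supplies
#'   the foreground masks.
#' @param n Sample size (default 100).
#' @param seed Integer seed for the sample.
#' @param thresholds,hot_cut Passed to [gradcam_score()].
#' @return `list(histogram =, mean =, scores =)` with the histogram over
#'   `{0, 1, 2, 3}`.
#' @export
score_gradcam_sample <- function(model, data, n = 100, seed = 1,
                                 thresholds = c(0.3, 0.6, 0.9),
                                 hot_cut = 0.5) {
  total <- dataset_size(data)
  assert_that(n <= total, "sample size exceeds the number of records")
  idx <- with_seed(seed, sample.int(total, n))
  scores <- vapply(idx, function(i) {
    hm <- gradcam(model, data$x[, , , i])
    as.integer(gradcam_score(hm, data$mask[, , i], thresholds, hot_cut))
  }, integer(1))
  hist <- table(factor(scores, levels = 0:3))
  list(histogram = stats::setNames(as.integer(hist), names(hist)),
       mean = mean(scores), scores = scores)
}

#' Extract flattened post-convolution features for a dataset
#'
#' @param model A `trained_model`.
#' @param data A dataset.
#' @return `N x feature_dim` matrix.
#' @export
extract_features <- function(model, data) {
  n <- dataset_size(data)
  out <- NULL
  for (start in seq(1, n, by = 64)) {
    idx <- start:min(start + 63, n)
    fwd <- model_forward(model$model, data$x[, , , idx, drop = FALSE])
    out <- rbind(out, fwd$feats)
  }
  out
}

#' Full evaluation report for one trained model
#'
#' Accuracy and confusion on both test domains, silhouette triple from a
#' joint t-SNE embedding of both test sets, and the Grad-CAM score histogram
#' on the photograph test set.
#'
#' @param model A `trained_model`.
#' @param test_synthetic,test_photo Test datasets.
#' @param tsne_seed Seed of the t-SNE embedding.
#' @param gradcam_n Grad-CAM sample size.
#' @param gradcam_seed Seed of the Grad-CAM sample.
#' @return An `eval_report` list.
#' @export
evaluate_model <- function(model, test_synthetic, test_photo, tsne_seed = 1,
                           gradcam_n = 100, gradcam_seed = 1) {
  feats <- rbind(extract_features(model, test_synthetic),
                 extract_features(model, test_photo))
  labels <- c(test_synthetic$classes[test_synthetic$y],
              test_photo$classes[test_photo$y])
  domains <- c(test_synthetic$domain, test_photo$domain)
  emb <- embed_tsne(feats, labels, domains, seed = tsne_seed)
  gc <- score_gradcam_sample(model, test_photo,
                             n = min(gradcam_n, dataset_size(test_photo)),
                             seed = gradcam_seed)
  structure(list(
    regime = model$config$regime,
    accuracy_synthetic = evaluate_accuracy(model, test_synthetic),
    accuracy_photo = evaluate_accuracy(model, test_photo),
    confusion_synthetic = confusion_matrix(model, test_synthetic),
    confusion_photo = confusion_matrix(model, test_photo),
    silhouettes = silhouette_scores(emb),
    embedding = emb,
    gradcam = gc,
    epochs = model$stopped_epoch
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report '%s': syn acc %.3f, photo acc %.3f, gradcam mean %.2f>\n",
              x$regime, x$accuracy_synthetic, x$accuracy_photo, x$gradcam$mean))
  invisible(x)
}
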