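# adapt_train: training regimes, early stopping, MMD objective, fine-tuning.

#' Stack image records into an array dataset
#'
#' @param records List of `image_record`s (all the same size; use [resize()]
#'   first if needed).
#' @param classes Class levels; defaults to the sorted species present.
#' @return List with `x` (`H x W x 3 x N`), `y` (integer labels), `specimen`,
#'   `domain`, `classes` and `mask` (`H x W x N` logical).
#' @export
as_image_dataset <- function(records, classes = NULL) {
  assert_that(length(records) > 0, "records must be nonempty")
  species <- vapply(records, `[[`, character(1), "species_id")
  classes <- classes %||% sort(unique(species))
  side <- dim(records[[1]]$pixels)[1:2]
  n <- length(records)
  x <- array(0, dim = c(side[1], side[2], 3, n))
  mask <- array(FALSE, dim = c(side[1], side[2], n))
  for (i in seq_len(n)) {
    x[, , , i] <- records[[i]]$pixels
    mask[, , i] <- records[[i]]$foreground_mask
  }
  list(x = x, y = match(species, classes),
       specimen = vapply(records, `[[`, character(1), "specimen_id"),
       domain = vapply(records, `[[`, character(1), "domain"),
       classes = classes, mask = mask)
}

dataset_take <- function(ds, idx) {
  list(x = ds$x[, , , idx, drop = FALSE], y = ds$y[idx],
       specimen = ds$specimen[idx], domain = ds$domain[idx],
       classes = ds$classes, mask = ds$mask[, , idx, drop = FALSE])
}

dataset_bind <- function(a, b) {
  assert_that(identical(a$classes, b$classes), "class levels must match")
  list(x = array(c(a$x, b$x), dim = c(dim(a$x)[1:3],
                                      dim(a$x)[4] + dim(b$x)[4])),
       y = c(a$y, b$y), specimen = c(a$specimen, b$specimen),
       domain = c(a$domain, b$domain), classes = a$classes,
       mask = array(c(a$mask, b$mask),
                    dim = c(dim(a$mask)[1:2], dim(a$mask)[3] + dim(b$mask)[3])))
}

dataset_size <- function(ds) length(ds$y)

#' Training configuration
#'
#' @param regime One of `"baseline"` (labelled synthetic), `"photo_baseline"`
#'   (all labelled photographs), `"photo_subset"` (labelled photograph
#'   subset), `"mmd"` (labelled synthetic + unlabelled photographs),
#'   `"supplemented"` (labelled synthetic + labelled photograph subset) or
#'   `"finetune"` (continue from MMD weights on the photograph subset).
#' @param lr Adam learning rate.
#' @param max_epochs Epoch budget (the classical digitisation protocol uses
#'   100).
#' @param patience Consecutive non-improving epochs tolerated before stopping
#'   (default 15). Improvement means a strictly better monitored value.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling init, shuffling and augmentation.
#' @param monitor `"train_domain_loss"` (early stopping on the training
#'   domain's test loss, the default protocol) or `"mean_test_accuracy"` (keep
#'   the epoch maximising the mean of the two domains' test accuracies, the
#'   automated stand-in for manual epoch selection used by supplemented and
#'   fine-tuned models).
#' @param mmd An [mmd_config()] (used by the `"mmd"` regime).
#' @param augment Optional [augment_config()] applied to labelled training
#'   records each epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(regime = c("baseline", "photo_baseline",
                                    "photo_subset", "mmd", "finetune",
                                    "supplemented"),
                         lr = 1e-3, max_epochs = 100, patience = 15,
                         batch_size = 32, seed = 1,
                         monitor = NULL, mmd = mmd_config(),
                         augment = NULL) {
  regime <- match.arg(regime)
  assert_that(patience <= max_epochs, "patience must not exceed max_epochs")
  monitor <- monitor %||%
    if (regime %in% c("supplemented", "finetune")) "mean_test_accuracy"
    else "train_domain_loss"
  assert_that(monitor %in% c("train_domain_loss", "mean_test_accuracy"),
              "unknown monitor")
  structure(list(regime = regime, lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 monitor = monitor, mmd = mmd, augment = augment),
            class = "train_config")
}

# Mean loss/accuracy of a model over a dataset, in forward-only minibatches.
evaluate_dataset <- function(model, ds, batch_size = 64) {
  n <- dataset_size(ds)
  loss <- 0
  correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fwd <- model_forward(model, ds$x[, , , idx, drop = FALSE])
    p <- pmax(fwd$probs[cbind(seq_along(idx), ds$y[idx])], 1e-12)
    loss <- loss - sum(log(p))
    correct <- correct + sum(max.col(fwd$probs, ties.method = "first") ==
                               ds$y[idx])
  }
  list(loss = loss / n, accuracy = correct / n)
}

regime_streams <- function(regime) {
  switch(regime,
    baseline = list(labelled = "train_synthetic"),
    photo_baseline = list(labelled = "train_photo"),
    photo_subset = list(labelled = "train_photo"),
    finetune = list(labelled = "train_photo"),
    mmd = list(labelled = "train_synthetic", unlabelled = "train_photo"),
    supplemented = list(labelled = c("train_synthetic", "train_photo"))
  )
}

#' Train a classifier under one regime
#'
#' The per-batch loss is cross-entropy on the labelled stream; the `"mmd"`
#' regime adds `lambda * MMD^2` between the flattened features of the
#' labelled synthetic batch and an unlabelled photograph batch. Training
#' stops early after `patience` consecutive epochs without improvement of the
#' monitored quantity, and the weights of the best monitored epoch are kept.
#'
#' @param data Named list of datasets (see [as_image_dataset()]):
#'   `train_synthetic` and/or `train_photo` as the regime requires, plus
#'   `test_synthetic` and `test_photo` for per-epoch evaluation.
#' @param cfg A [train_config()].
#' @param backbone A [backbone_config()].
#' @param start Optional `trained_model` whose weights initialise training
#'   (used by [finetune()]).
#' @return A `trained_model`: the fitted `ma_model`, the per-epoch `history`
#'   (losses and accuracies on both test domains), `stopped_epoch`,
#'   `best_epoch` and a config snapshot.
#' @export
train <- function(data, cfg, backbone = backbone_config("tiny"),
                  start = NULL) {
  assert_that(inherits(cfg, "train_config"), "cfg must be a train_config")
  streams <- regime_streams(cfg$regime)
  for (s in unlist(streams)) {
    if (is.null(data[[s]])) {
      stop("regime '", cfg$regime, "' requires a '", s, "' data stream")
    }
  }
  assert_that(!is.null(data$test_synthetic) && !is.null(data$test_photo),
              "both test_synthetic and test_photo datasets are required")

  lab <- data[[streams$labelled[1]]]
  if (length(streams$labelled) > 1) {
    for (s in streams$labelled[-1]) lab <- dataset_bind(lab, data[[s]])
  }
  unlab <- if (!is.null(streams$unlabelled)) data[[streams$unlabelled]]
  n_classes <- length(lab$classes)
  side <- dim(lab$x)[1]

  if (is.null(start)) {
    model <- build_classifier(backbone, n_classes, side,
                              seed = derive_seed(cfg$seed, 11L))
  } else {
    model <- start$model
    assert_that(model$input_side == side && model$n_classes == n_classes,
                "start model architecture does not match the data")
  }

  # training domain for the early-stopping monitor
  monitor_photo <- cfg$regime %in% c("photo_baseline", "photo_subset",
                                     "finetune")

  bw <- cfg$mmd$bandwidths
  opt <- adam_init(model$params)
  t_step <- 0
  history <- data.frame()
  best_metric <- Inf
  best_params <- model$params
  best_epoch <- 0L
  bad_epochs <- 0L
  n <- dataset_size(lab)
  nb <- max(1, ceiling(n / cfg$batch_size))

  if (cfg$max_epochs == 0) {
    return(structure(list(model = model, history = history,
                          stopped_epoch = 0L, best_epoch = 0L,
                          config = cfg, backbone = backbone,
                          classes = lab$classes,
                          provenance = if (!is.null(start))
                            list(start_stopped_epoch = start$stopped_epoch)),
                     class = "trained_model"))
  }

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 100L + epoch), sample.int(n))
    if (!is.null(unlab)) {
      u_ord <- with_seed(derive_seed(cfg$seed, 500L + epoch),
                         sample.int(dataset_size(unlab)))
    }
    xs <- lab$x
    if (!is.null(cfg$augment)) {
      # per-epoch record-level augmentation of the labelled stream
      for (i in seq_len(n)) {
        rec <- image_record(lab$x[, , , i], lab$mask[, , i])
        rec <- augment(rec, cfg$augment,
                       seed = derive_seed(cfg$seed, epoch, i))
        xs[, , , i] <- rec$pixels
      }
    }
    epoch_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, n)]
      X <- xs[, , , idx, drop = FALSE]
      y <- lab$y[idx]
      fwd <- model_forward(model, X, want_cache = TRUE)
      ce <- cross_entropy(fwd$probs, y)
      loss <- ce$loss
      dfeats_extra <- NULL
      if (cfg$regime == "mmd" && cfg$mmd$lambda > 0) {
        m_u <- dataset_size(unlab)
        u_pos <- ((b - 1) * cfg$batch_size) %% m_u
        u_idx <- u_ord[(u_pos + seq_len(min(cfg$batch_size, m_u)) - 1) %% m_u + 1]
        fwd_u <- model_forward(model, unlab$x[, , , u_idx, drop = FALSE],
                               want_cache = TRUE)
        bws <- bw %||% (median_bandwidth(fwd$feats, fwd_u$feats) *
                          cfg$mmd$bandwidth_multipliers)
        mg <- mmd2_with_grad(fwd$feats, fwd_u$feats, bws)
        loss <- loss + cfg$mmd$lambda * mg$value
        dfeats_extra <- cfg$mmd$lambda * mg$dA
        grads_u <- model_backward(model, fwd_u,
                                  matrix(0, length(u_idx), n_classes),
                                  dfeats_extra = cfg$mmd$lambda * mg$dB)
      }
      grads <- model_backward(model, fwd, ce$dlogits,
                              dfeats_extra = dfeats_extra)
      if (cfg$regime == "mmd" && cfg$mmd$lambda > 0) {
        grads <- add_grads(grads, grads_u)
      }
      if (!all(is.finite(unlist(lapply(grads, unlist)))) ||
          !is.finite(loss)) {
        stop("training diverged (non-finite loss or gradients)")
      }
      t_step <- t_step + 1
      st <- adam_step(model$params, grads, opt, cfg$lr, t_step)
      model$params <- st$p
      opt <- st$s
      epoch_loss <- epoch_loss + loss
    }

    ev_syn <- evaluate_dataset(model, data$test_synthetic)
    ev_photo <- evaluate_dataset(model, data$test_photo)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / nb,
      syn_test_loss = ev_syn$loss, syn_test_acc = ev_syn$accuracy,
      photo_test_loss = ev_photo$loss, photo_test_acc = ev_photo$accuracy
    ))

    metric <- if (cfg$monitor == "train_domain_loss") {
      if (monitor_photo) ev_photo$loss else ev_syn$loss
    } else {
      -(ev_syn$accuracy + ev_photo$accuracy) / 2
    }
    if (metric < best_metric) {
      best_metric <- metric
      best_params <- model$params
      best_epoch <- epoch
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$patience) break
    }
  }

  model$params <- best_params
  structure(list(model = model, history = history,
                 stopped_epoch = nrow(history), best_epoch = best_epoch,
                 config = cfg, backbone = backbone, classes = lab$classes,
                 provenance = if (!is.null(start))
                   list(start_stopped_epoch = start$stopped_epoch)),
            class = "trained_model")
}

add_grads <- function(a, b) {
  if (!is.list(a)) return(a + b)
  for (i in seq_along(a)) a[[i]] <- add_grads(a[[i]], b[[i]])
  a
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model: regime '%s', %d classes, %d epochs (best %d)>\n",
              x$config$regime, x$model$n_classes, x$stopped_epoch,
              x$best_epoch))
  invisible(x)
}

#' Fine-tune a trained model on the labelled photograph subset
#'
#' Continues training from the supplied model's weights (canonically the MMD
#' model) with plain cross-entropy on the photograph subset. The returned
#' history carries a provenance link recording the start model's stopped
#' epoch.
#'
#' @param start A `trained_model`.
#' @param data Data bundle with `train_photo`, `test_synthetic`, `test_photo`.
#' @param cfg A [train_config()] with `regime = "finetune"`.
#' @return A `trained_model`.
#' @export
finetune <- function(start, data, cfg = train_config("finetune")) {
  assert_that(inherits(start, "trained_model"), "start must be a trained_model")
  assert_that(cfg$regime == "finetune", "cfg$regime must be 'finetune'")
  train(data, cfg, backbone = start$backbone, start = start)
}

#' Pick the epoch maximising mean test accuracy across both domains
#'
#' An explicit, reproducible criterion standing in for manual epoch
#' selection: the argmax of `(synthetic accuracy + photograph accuracy) / 2`,
#' ties broken toward the earliest epoch.
#'
#' @param history A training history with `syn_test_acc` and
#'   `photo_test_acc` columns.
#' @return Integer epoch index.
#' @export
select_best_epoch <- function(history) {
  assert_that(is.data.frame(history) && nrow(history) > 0,
              "history must be a nonempty data frame")
  assert_that(all(c("syn_test_acc", "photo_test_acc") %in% names(history)),
              "history must carry both domains' test accuracies")
  crit <- (history$syn_test_acc + history$photo_test_acc) / 2
  which.max(crit)  # which.max returns the first maximum
}

#' Class-probability predictions
#'
#' @param object A `trained_model`.
#' @param newdata A dataset (see [as_image_dataset()]) or an image array.
#' @param ... Unused.
#' @return `N x C` matrix of class probabilities.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  n <- dim(x)[4]
  out <- NULL
  for (start in seq(1, n, by = 64)) {
    idx <- start:min(start + 63, n)
    fwd <- model_forward(object$model, x[, , , idx, drop = FALSE])
    out <- rbind(out, fwd$probs)
  }
  out
}
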