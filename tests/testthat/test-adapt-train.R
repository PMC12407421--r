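test_that("conv/dense backward passes match finite differences", {
  set.seed(7)
  model <- build_classifier(backbone_config("tiny"), 3, input_side = 8,
                            seed = 2)
  X <- array(stats::runif(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  y <- c(1L, 3L)
  loss_at <- function(params) {
    m <- model
    m$params <- params
    fwd <- model_forward(m, X)
    morphadapt:::cross_entropy(fwd$probs, y)$loss
  }
  fwd <- model_forward(model, X, want_cache = TRUE)
  ce <- morphadapt:::cross_entropy(fwd$probs, y)
  g <- morphadapt:::model_backward(model, fwd, ce$dlogits)
  eps <- 1e-6
  check <- function(get, set, gmat, n_checks = 4) {
    n_checks <- min(n_checks, length(get(model$params)))
    for (k in sample(length(get(model$params)), n_checks)) {
      p_up <- model$params
      v <- get(p_up); v[k] <- v[k] + eps; p_up <- set(p_up, v)
      p_dn <- model$params
      v <- get(p_dn); v[k] <- v[k] - eps; p_dn <- set(p_dn, v)
      fd <- (loss_at(p_up) - loss_at(p_dn)) / (2 * eps)
      expect_equal(gmat[k], fd, tolerance = 1e-5)
    }
  }
  check(function(p) p$conv[[1]]$W,
        function(p, v) { p$conv[[1]]$W <- v; p }, g$conv[[1]]$W)
  check(function(p) p$conv[[2]]$W,
        function(p, v) { p$conv[[2]]$W <- v; p }, g$conv[[2]]$W)
  check(function(p) p$fc1$W, function(p, v) { p$fc1$W <- v; p }, g$fc1$W)
  check(function(p) p$fc2$W, function(p, v) { p$fc2$W <- v; p }, g$fc2$W)
  check(function(p) p$fc2$b, function(p, v) { p$fc2$b <- v; p }, g$fc2$b)
})

test_that("classifier construction validates its inputs", {
  expect_error(build_classifier(backbone_config("tiny"), 1), "n_classes")
  expect_error(build_classifier(backbone_config("tiny"), 2, input_side = 10),
               "divisible")
  expect_error(backbone_config("tiny", pretrained = TRUE), "vgg19_like")
  expect_error(backbone_config("vgg19_like", pretrained = TRUE),
               "weights_path")
  # vgg19-like stack is constructible and carries 16 conv layers
  vg <- build_classifier(backbone_config("vgg19_like"), 2, input_side = 64)
  expect_length(vg$params$conv, 16)
  # deterministic initialisation
  m1 <- build_classifier(backbone_config("tiny"), 2, 16, seed = 5)
  m2 <- build_classifier(backbone_config("tiny"), 2, 16, seed = 5)
  expect_identical(m1$params, m2$params)
})

test_that("softmax probabilities are valid and forward features finite", {
  m <- build_classifier(backbone_config("tiny"), 4, 16, seed = 1)
  X <- array(stats::runif(16 * 16 * 3 * 3), dim = c(16, 16, 3, 3))
  fwd <- model_forward(m, X, want_cache = TRUE)
  expect_equal(rowSums(fwd$probs), rep(1, 3), tolerance = 1e-12)
  expect_true(all(fwd$probs >= 0))
  expect_equal(ncol(fwd$feats), m$feature_dim)
  expect_true(all(is.finite(fwd$feats)))
  expect_equal(dim(fwd$conv_final)[1:2], rep(m$conv_side, 2))
})

test_that("training learns the toy problem, deterministically", {
  data <- toy_bundle()
  cfg <- train_config("baseline", max_epochs = 6, patience = 6,
                      batch_size = 8, seed = 3)
  m1 <- train(data, cfg)
  m2 <- train(data, cfg)
  expect_identical(m1$model$params, m2$model$params)
  expect_identical(m1$history, m2$history)
  expect_gte(evaluate_accuracy(m1, data$test_synthetic), 0.9)
  expect_equal(nrow(m1$history), m1$stopped_epoch)
  expect_true(all(c("epoch", "train_loss", "syn_test_loss", "syn_test_acc",
                    "photo_test_loss", "photo_test_acc") %in%
                    names(m1$history)))
})

test_that("early stopping restores the best-epoch weights", {
  data <- toy_bundle()
  cfg <- train_config("baseline", max_epochs = 8, patience = 2,
                      batch_size = 8, seed = 4)
  m <- train(data, cfg)
  expect_lte(m$best_epoch, m$stopped_epoch)
  # the kept weights reproduce the monitored (synthetic test) loss of the
  # best epoch, not the last one
  ev <- morphadapt:::evaluate_dataset(m$model, data$test_synthetic)
  expect_equal(ev$loss, m$history$syn_test_loss[m$best_epoch],
               tolerance = 1e-10)
  expect_equal(m$best_epoch, which.min(m$history$syn_test_loss))
})

test_that("regimes demand their data streams and bind them correctly", {
  data <- toy_bundle()
  expect_error(train(data["test_synthetic"],
                     train_config("baseline", max_epochs = 1, patience = 1)),
               "train_synthetic")
  expect_error(train(list(train_synthetic = data$train_synthetic,
                          test_synthetic = data$test_synthetic),
                     train_config("baseline", max_epochs = 1, patience = 1)),
               "test_photo")
  expect_error(train(data[c("train_synthetic", "test_synthetic",
                            "test_photo")],
                     train_config("mmd", max_epochs = 1, patience = 1)),
               "train_photo")

  # photo regimes monitor the photo-domain test loss
  cfgp <- train_config("photo_baseline", max_epochs = 5, patience = 2,
                       batch_size = 8, seed = 5)
  mp <- train(data, cfgp)
  expect_equal(mp$best_epoch, which.min(mp$history$photo_test_loss))

  # supplemented monitors mean test accuracy by default
  expect_equal(train_config("supplemented", max_epochs = 2,
                            patience = 1)$monitor, "mean_test_accuracy")
  expect_equal(train_config("baseline", max_epochs = 2,
                            patience = 1)$monitor, "train_domain_loss")
})

test_that("the MMD regime trains and shrinks the feature discrepancy", {
  data <- toy_bundle()
  cfg0 <- train_config("mmd", max_epochs = 0, patience = 0, seed = 6,
                       mmd = mmd_config(lambda = 1))
  cfg <- train_config("mmd", max_epochs = 6, patience = 6, batch_size = 8,
                      seed = 6, mmd = mmd_config(lambda = 1))
  m0 <- train(data, cfg0)     # untrained reference
  m <- train(data, cfg)
  f_syn <- extract_features(m, data$test_synthetic)
  f_pho <- extract_features(m, data$test_photo)
  g_syn <- extract_features(m0, data$test_synthetic)
  g_pho <- extract_features(m0, data$test_photo)
  cfgm <- mmd_config()
  expect_lt(mmd2(f_syn, f_pho, cfgm) /
              max(mmd2(g_syn, g_pho, cfgm), 1e-12), 1.5)
  expect_gte(evaluate_accuracy(m, data$test_synthetic), 0.75)
})

test_that("finetune continues from given weights and records provenance", {
  data <- toy_bundle()
  base <- train(data, train_config("mmd", max_epochs = 3, patience = 3,
                                   batch_size = 8, seed = 7))
  ft <- finetune(base, data, train_config("finetune", max_epochs = 3,
                                          patience = 3, batch_size = 8,
                                          seed = 8))
  expect_equal(ft$provenance$start_stopped_epoch, base$stopped_epoch)
  expect_error(finetune(base, data, train_config("baseline", max_epochs = 1,
                                                 patience = 1)),
               "finetune")
  expect_error(finetune(list(), data), "trained_model")
  # architecture mismatch is rejected
  wrong <- toy_bundle()
  wrong$train_photo <- make_toy_ds(4, side = 32, seed = 1, domain = "photo")
  wrong$test_synthetic <- make_toy_ds(2, side = 32, seed = 2)
  wrong$test_photo <- make_toy_ds(2, side = 32, seed = 3, domain = "photo")
  expect_error(finetune(base, wrong,
                        train_config("finetune", max_epochs = 1,
                                     patience = 1)), "architecture")
})

test_that("select_best_epoch maximises mean accuracy, first on ties", {
  h <- data.frame(syn_test_acc = c(0.5, 0.9, 0.9, 0.7),
                  photo_test_acc = c(0.5, 0.7, 0.7, 0.9))
  expect_equal(select_best_epoch(h), 2)
  expect_error(select_best_epoch(data.frame()), "nonempty")
  expect_error(select_best_epoch(data.frame(syn_test_acc = 1)), "both domains")
})

test_that("train_config validation and predict() shapes", {
  expect_error(train_config("baseline", max_epochs = 2, patience = 5),
               "patience")
  expect_error(train_config("nonsense"), "arg")
  data <- toy_bundle()
  m <- train(data, train_config("baseline", max_epochs = 2, patience = 2,
                                batch_size = 8, seed = 9))
  p <- predict(m, data$test_photo)
  expect_equal(dim(p), c(dataset_size_(data$test_photo), 2))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-12)
})
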