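# Minimal but complete experiment configuration, kept tiny for speed.
micro_config <- function() {
  list(
    forge = list(n_species = 2, specimens_per_species = 2,
                 photo_specimens_per_species = 2, seed = 5),
    viewsphere = list(yaw_step = 90, ring_pitches = list(0), include_poles = FALSE,
                      resolution = 16,
                      photo = list(background_marking_density = 1,
                                   brightness_jitter_sd = 0.1,
                                   color_cast_strength = 0.1,
                                   blur_sigma = 0.5, noise_sd = 0.02,
                                   distance_jitter_sd = 0.02,
                                   session_confound = FALSE)),
    datapipe = list(test_fraction = 0.2, subset_fraction = 0.5),
    training = list(backbone = "tiny", lr = 1e-3, max_epochs = 2, patience = 2,
                    batch_size = 8, seed = 1, lambda = 1,
                    regimes = list("baseline")),
    evaluation = list(tsne_seed = 1, gradcam_n = 6, gradcam_seed = 1),
    log_level = "quiet"
  )
}

test_that("shipped configuration profiles load and validate", {
  desk <- default_experiment_config("desk_test")
  expect_equal(desk$forge$n_species, 4)
  expect_equal(desk$training$backbone, "tiny")

  full <- default_experiment_config("full_scale")
  expect_equal(full$forge$n_species, 16)
  expect_equal(full$forge$specimens_per_species, 30)
  expect_equal(full$viewsphere$resolution, 720)
  # its view sphere is the canonical 92-pose lattice
  poses <- view_sphere_poses(view_sphere_spec(
    full$viewsphere$yaw_step, unlist(full$viewsphere$ring_pitches),
    isTRUE(full$viewsphere$include_poles)))
  expect_length(poses, 92)
  expect_setequal(unlist(full$training$regimes),
                  c("baseline", "photo_baseline", "photo_subset", "mmd",
                    "finetune", "supplemented"))

  expect_error(load_experiment_config("/nonexistent/file.yaml"), "not found")
})

test_that("configuration validation flags missing fields and bad regimes", {
  good <- micro_config()
  expect_identical(morphadapt:::validate_experiment_config(good), good)
  bad <- good
  bad$forge$seed <- NULL
  expect_error(morphadapt:::validate_experiment_config(bad), "seed")
  bad2 <- good
  bad2$datapipe <- NULL
  expect_error(morphadapt:::validate_experiment_config(bad2), "datapipe")
  bad3 <- good
  bad3$training$regimes <- list("baseline", "mystery")
  expect_error(morphadapt:::validate_experiment_config(bad3), "regime")

  h1 <- morphadapt:::config_hash(good)
  expect_identical(h1, morphadapt:::config_hash(good))
  changed <- good
  changed$forge$seed <- 6
  expect_false(identical(h1, morphadapt:::config_hash(changed)))
})

test_that("build_experiment_data assembles leak-free two-domain datasets", {
  cfg <- micro_config()
  data <- build_experiment_data(cfg)
  expect_named(data, c("train_synthetic", "test_synthetic", "train_photo",
                       "train_photo_subset", "test_photo", "plan_synthetic",
                       "plan_photo", "plan_photo_subset", "scan_bank",
                       "photo_bank"), ignore.order = TRUE)
  # 2 species x 1 train specimen x 4 poses per domain
  expect_equal(length(data$train_synthetic$y), 8)
  expect_equal(length(data$test_synthetic$y), 8)
  expect_identical(data$train_synthetic$classes, data$test_photo$classes)
  expect_true(all(data$train_photo$domain == "photo"))
  expect_true(all(data$train_synthetic$domain == "synthetic"))
  # no specimen appears in both a train and a test partition
  expect_length(intersect(data$train_synthetic$specimen,
                          data$test_synthetic$specimen), 0)
  expect_length(intersect(data$train_photo$specimen,
                          data$test_photo$specimen), 0)
  # the two domains never share an individual
  syn_ids <- vapply(data$scan_bank, `[[`, character(1), "specimen_id")
  pho_ids <- vapply(data$photo_bank, `[[`, character(1), "specimen_id")
  expect_length(intersect(syn_ids, pho_ids), 0)
  # the subset's training specimens are a subset of the full photo plan's
  expect_true(all(data$train_photo_subset$specimen %in%
                    data$train_photo$specimen))

  # optional resize produces the requested side
  cfg$datapipe$resize_side <- 24
  data24 <- build_experiment_data(cfg)
  expect_equal(dim(data24$train_synthetic$x)[1:2], c(24, 24))
})

test_that("regime_data routes the right streams to each regime", {
  cfg <- micro_config()
  data <- build_experiment_data(cfg)
  rb <- morphadapt:::regime_data("baseline", data)
  expect_named(rb, c("test_synthetic", "test_photo", "train_synthetic"),
               ignore.order = TRUE)
  rm_ <- morphadapt:::regime_data("mmd", data)
  expect_identical(rm_$train_photo, data$train_photo)
  rs <- morphadapt:::regime_data("supplemented", data)
  expect_identical(rs$train_photo, data$train_photo_subset)
  rf <- morphadapt:::regime_data("finetune", data)
  expect_identical(rf$train_photo, data$train_photo_subset)
  rp <- morphadapt:::regime_data("photo_baseline", data)
  expect_identical(rp$train_photo, data$train_photo)
})

test_that("run_experiment produces reports, a comparison table and artifacts", {
  cfg <- micro_config()
  out <- withr::local_tempdir()
  res <- run_experiment(cfg, out_dir = out)
  expect_named(res$reports, "baseline")
  expect_equal(nrow(res$comparison), 1)
  expect_setequal(names(res$comparison),
                  c("regime", "synthetic_accuracy", "photo_accuracy",
                    "epochs", "silhouette_synthetic", "silhouette_photo",
                    "silhouette_combined", "gradcam_mean"))
  expect_true(file.exists(file.path(out, "comparison.csv")))
  expect_true(file.exists(file.path(out, "report_baseline.json")))
  expect_true(file.exists(file.path(out, "history_baseline.csv")))
  expect_true(file.exists(file.path(out, "config_sidecar.json")))
  side <- jsonlite::read_json(file.path(out, "config_sidecar.json"))
  expect_equal(side$config_hash, morphadapt:::config_hash(
    morphadapt:::validate_experiment_config(cfg)))

  # finetune without mmd in the same experiment is rejected up front
  bad <- cfg
  bad$training$regimes <- list("finetune")
  expect_error(run_experiment(bad), "requires the mmd regime")
})

test_that("the cli reports usage, config and runtime errors by status", {
  expect_equal(suppressMessages(cli(c("--help"))), 0L)
  expect_equal(suppressMessages(cli(character())), 2L)
  expect_equal(suppressMessages(cli(c("dance"))), 2L)
  expect_equal(suppressMessages(cli(c("forge"))), 2L)
  expect_equal(suppressMessages(cli(c("--bogus-flag", "forge"))), 2L)
  # a missing config file is named in the message
  msgs <- capture.output(
    status <- cli(c("forge", "--config", "/no/such/config.yaml")),
    type = "message")
  expect_equal(status, 2L)
  expect_true(any(grepl("/no/such/config.yaml", msgs)))
})

test_that("cli forge and split subcommands write their artifacts", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(micro_config(), cfg_path)
  out <- withr::local_tempdir()
  expect_equal(suppressMessages(
    cli(c("forge", "--config", cfg_path, "--out", out,
          "--log-level", "quiet"))), 0L)
  man <- utils::read.csv(file.path(out, "forge_manifest.csv"))
  expect_equal(nrow(man), 8)   # 2 species x (2 scan + 2 photo) specimens
  expect_true(all(file.exists(file.path(out, paste0(man$specimen_id, ".obj")))))
  # forged meshes are readable OBJ files
  m <- read_obj(file.path(out, paste0(man$specimen_id[1], ".obj")))
  expect_s3_class(m, "tri_mesh")

  out2 <- withr::local_tempdir()
  expect_equal(suppressMessages(
    cli(c("split", "--config", cfg_path, "--out", out2,
          "--log-level", "quiet"))), 0L)
  for (f in c("split_synthetic.json", "split_photo.json",
              "split_photo_subset.json")) {
    expect_true(file.exists(file.path(out2, f)))
  }
  plan <- jsonlite::read_json(file.path(out2, "split_synthetic.json"),
                              simplifyVector = TRUE)
  expect_length(intersect(plan$train, plan$test), 0)
})
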