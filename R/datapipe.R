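# datapipe: specimen-level splitting, subset selection, augmentation, resize.

#' Specimen-level train/test split
#'
#' Splits at the specimen level, within species, so that all images of one
#' individual land in exactly one partition. Per species,
#' `floor(n * test_fraction)` specimens (at least 1, at most n - 1) go to the
#' test set; this reproduces the canonical 30 -> 24:6 and 29 -> 24:5
#' assignments at a 0.2 test fraction.
#'
#' @param records List of `image_record`s, or a manifest data frame with
#'   columns `specimen_id` and `species_id`.
#' @param test_fraction Test fraction in (0, 1).
#' @param seed Integer seed; the plan is a pure function of inputs and seed.
#' @return A `split_plan`: `list(train, test, unused, counts, seed)` where the
#'   first three are character vectors of specimen ids and `counts` is a
#'   per-species table.
#' @export
split_by_specimen <- function(records, test_fraction = 0.2, seed = 1) {
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must be in (0, 1)")
  tab <- specimen_table(records)
  plan <- list(train = character(0), test = character(0),
               unused = character(0), seed = as.integer(seed),
               species = stats::setNames(tab$species_id, tab$specimen_id))
  counts <- list()
  for (sp in unique(tab$species_id)) {
    ids <- sort(tab$specimen_id[tab$species_id == sp])
    n <- length(ids)
    if (n < 2) {
      stop("split infeasible: species ", sp, " has fewer than 2 specimens")
    }
    n_test <- min(max(floor(n * test_fraction), 1L), n - 1L)
    test_ids <- with_seed(derive_seed(seed, string_hash(sp)),
                          sample(ids, n_test))
    plan$test <- c(plan$test, test_ids)
    plan$train <- c(plan$train, setdiff(ids, test_ids))
    counts[[sp]] <- data.frame(species_id = sp, n_train = n - n_test,
                               n_test = n_test, n_unused = 0L,
                               stringsAsFactors = FALSE)
  }
  plan$counts <- do.call(rbind, counts)
  rownames(plan$counts) <- NULL
  structure(plan, class = "split_plan")
}

# Unique (specimen_id, species_id) pairs from records or a manifest.
specimen_table <- function(records) {
  if (is.data.frame(records)) {
    tab <- unique(records[, c("specimen_id", "species_id")])
  } else {
    assert_that(length(records) > 0, "records must be nonempty")
    tab <- unique(data.frame(
      specimen_id = vapply(records, `[[`, character(1), "specimen_id"),
      species_id = vapply(records, `[[`, character(1), "species_id"),
      stringsAsFactors = FALSE
    ))
  }
  tab
}

#' Retain a per-species fraction of a plan's training specimens
#'
#' Models trained on a reduced labelled pool keep `floor(keep_fraction * n)`
#' training specimens per species (at least 1); the rest are marked unused.
#' The test partition is untouched, so an 8:2 plan at `keep_fraction = 0.25`
#' becomes the 2:2:6 train:test:unused layout.
#'
#' @param plan A `split_plan`.
#' @param keep_fraction Fraction of training specimens to retain, in (0, 1].
#' @param seed Integer seed.
#' @return A new `split_plan` with updated train/unused sets and counts.
#' @export
subset_training_specimens <- function(plan, keep_fraction, seed = 1) {
  assert_that(inherits(plan, "split_plan"), "plan must be a split_plan")
  assert_that(keep_fraction > 0 && keep_fraction <= 1,
              "keep_fraction must be in (0, 1]")
  if (keep_fraction == 1) return(plan)
  species_of <- specimen_species_map(plan)
  new_train <- character(0)
  new_unused <- plan$unused
  for (sp in plan$counts$species_id) {
    ids <- sort(plan$train[species_of[plan$train] == sp])
    n_keep <- max(1L, floor(keep_fraction * length(ids)))
    keep_ids <- with_seed(derive_seed(seed, string_hash(sp), 7L),
                          sample(ids, n_keep))
    new_train <- c(new_train, keep_ids)
    new_unused <- c(new_unused, setdiff(ids, keep_ids))
    i <- plan$counts$species_id == sp
    plan$counts$n_unused[i] <- plan$counts$n_unused[i] +
      (length(ids) - n_keep)
    plan$counts$n_train[i] <- n_keep
  }
  plan$train <- new_train
  plan$unused <- new_unused
  validate_split_plan(plan)
  plan
}

specimen_species_map <- function(plan) plan$species

validate_split_plan <- function(plan) {
  all_ids <- c(plan$train, plan$test, plan$unused)
  assert_that(!anyDuplicated(all_ids),
              "split plan assigns a specimen to more than one partition")
  invisible(plan)
}

#' Partition of a specimen id under a plan
#' @param plan A `split_plan`.
#' @param specimen_id Character vector of ids.
#' @return Character vector: "train", "test", "unused" or NA.
#' @export
plan_partition <- function(plan, specimen_id) {
  out <- rep(NA_character_, length(specimen_id))
  out[specimen_id %in% plan$train] <- "train"
  out[specimen_id %in% plan$test] <- "test"
  out[specimen_id %in% plan$unused] <- "unused"
  out
}

#' Select records belonging to one partition of a plan
#' @param records List of `image_record`s.
#' @param plan A `split_plan`.
#' @param partition One of "train", "test", "unused".
#' @return The matching sub-list.
#' @export
filter_records <- function(records, plan, partition = "train") {
  ids <- vapply(records, `[[`, character(1), "specimen_id")
  records[plan_partition(plan, ids) == partition]
}

#' Serialize / read a split plan as JSON
#' @param plan A `split_plan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(train = plan$train, test = plan$test,
                            unused = plan$unused, seed = plan$seed),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Augmentation configuration
#'
#' Defaults are mild: up to 10% translation, 50% horizontal flips, and
#' +-0.2 multiplicative jitter on brightness/contrast/saturation with +-0.05
#' hue rotation. Test images are never augmented.
#'
#' @param translate_frac Max |shift| as a fraction of the frame side, in
#'   `[0, 0.5]`.
#' @param hflip_prob Horizontal flip probability.
#' @param brightness,contrast,saturation Multiplicative jitter half-ranges.
#' @param hue Additive hue rotation half-range (fraction of the hue circle).
#' @return An `augment_config` object.
#' @export
augment_config <- function(translate_frac = 0.1, hflip_prob = 0.5,
                           brightness = 0.2, contrast = 0.2,
                           saturation = 0.2, hue = 0.05) {
  assert_that(translate_frac >= 0 && translate_frac <= 0.5,
              "translate_frac must be in [0, 0.5]")
  assert_that(hflip_prob >= 0 && hflip_prob <= 1,
              "hflip_prob must be in [0, 1]")
  assert_that(all(c(brightness, contrast, saturation, hue) >= 0),
              "jitter ranges must be non-negative")
  structure(list(translate_frac = translate_frac, hflip_prob = hflip_prob,
                 brightness = brightness, contrast = contrast,
                 saturation = saturation, hue = hue),
            class = "augment_config")
}

# Numeric HSV -> RGB (h, s, v in [0,1]); exact inverse of grDevices::rgb2hsv
# up to floating point, needed because base R exposes no numeric hsv2rgb.
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Integer-pixel shift with edge replication (FALSE-fill for logical masks).
shift_plane <- function(m, dy, dx, replicate_edges = TRUE) {
  nr <- nrow(m)
  nc <- ncol(m)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  if (replicate_edges) {
    src_r <- clamp(src_r, 1, nr)
    src_c <- clamp(src_c, 1, nc)
    m[src_r, src_c, drop = FALSE]
  } else {
    out <- matrix(FALSE, nr, nc)
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
    out
  }
}

#' Augment an image record
#'
#' Applies, in order: integer-pixel vertical/horizontal translation, a
#' horizontal flip, then brightness, contrast, saturation and hue jitter.
#' Labels, specimen id and domain tag are never changed; the foreground mask
#' is translated/flipped alongside the pixels. An all-zero configuration is
#' the identity, and the output is deterministic given the seed.
#'
#' @param img An `image_record`.
#' @param cfg An [augment_config()].
#' @param seed Integer seed.
#' @return The augmented `image_record`.
#' @export
augment <- function(img, cfg = augment_config(), seed = 1) {
  assert_that(inherits(img, "image_record"), "img must be an image_record")
  assert_that(inherits(cfg, "augment_config"), "cfg must be an augment_config")
  with_seed(seed, {
    pix <- img$pixels
    mask <- img$foreground_mask
    side <- nrow(mask)

    dx <- round(stats::runif(1, -1, 1) * cfg$translate_frac * side)
    dy <- round(stats::runif(1, -1, 1) * cfg$translate_frac * side)
    if (dx != 0 || dy != 0) {
      for (ch in 1:3) pix[, , ch] <- shift_plane(pix[, , ch], dy, dx)
      mask <- shift_plane(mask, dy, dx, replicate_edges = FALSE)
    }

    if (stats::runif(1) < cfg$hflip_prob) {
      pix <- pix[, rev(seq_len(ncol(mask))), , drop = FALSE]
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }

    bright <- stats::runif(1, 1 - cfg$brightness, 1 + cfg$brightness)
    contr <- stats::runif(1, 1 - cfg$contrast, 1 + cfg$contrast)
    satur <- stats::runif(1, 1 - cfg$saturation, 1 + cfg$saturation)
    hshift <- stats::runif(1, -cfg$hue, cfg$hue)

    if (bright != 1) pix <- pix * bright
    if (contr != 1) pix <- (pix - 0.5) * contr + 0.5
    if (satur != 1) {
      gray <- 0.299 * pix[, , 1] + 0.587 * pix[, , 2] + 0.114 * pix[, , 3]
      for (ch in 1:3) pix[, , ch] <- gray + satur * (pix[, , ch] - gray)
    }
    if (hshift != 0) {
      pix <- clamp(pix)
      flat <- rbind(as.vector(pix[, , 1]), as.vector(pix[, , 2]),
                    as.vector(pix[, , 3]))
      hsv <- grDevices::rgb2hsv(flat, maxColorValue = 1)
      rgb <- hsv_to_rgb(hsv[1, ] + hshift, hsv[2, ], hsv[3, ])
      dimn <- dim(pix)
      pix <- array(c(rgb[, 1], rgb[, 2], rgb[, 3]), dim = dimn)
    }
    image_record(clamp(pix), mask, img$species_id, img$specimen_id,
                 img$domain, img$pose)
  })
}

#' Resize an image record
#'
#' Bilinear resampling of the pixels (half-pixel-centre mapping, so resizing
#' to the input size is exactly the identity); nearest-neighbour resampling
#' of the foreground mask.
#'
#' @param img An `image_record`.
#' @param side Output side in pixels (>= 8).
#' @return The resized `image_record`.
#' @export
resize <- function(img, side) {
  assert_that(inherits(img, "image_record"), "img must be an image_record")
  assert_that(side >= 8, "side must be at least 8")
  side <- as.integer(side)
  n_in <- nrow(img$foreground_mask)
  if (side == n_in && side == ncol(img$foreground_mask)) return(img)

  map_axis <- function(n_out, n) {
    src <- (seq_len(n_out) - 0.5) * (n / n_out) - 0.5
    lo <- clamp(floor(src), 0, n - 1)
    frac <- clamp(src - lo, 0, 1)
    list(lo = as.integer(lo) + 1L, hi = as.integer(clamp(lo + 1, 0, n - 1)) + 1L,
         frac = frac)
  }
  ry <- map_axis(side, nrow(img$foreground_mask))
  rx <- map_axis(side, ncol(img$foreground_mask))
  wy <- matrix(ry$frac, side, side)
  wx <- matrix(rx$frac, side, side, byrow = TRUE)

  out <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) {
    p <- img$pixels[, , ch]
    out[, , ch] <-
      (1 - wy) * (1 - wx) * p[ry$lo, rx$lo] +
      (1 - wy) * wx * p[ry$lo, rx$hi] +
      wy * (1 - wx) * p[ry$hi, rx$lo] +
      wy * wx * p[ry$hi, rx$hi]
  }
  near <- function(r) ifelse(r$frac < 0.5, r$lo, r$hi)
  mask <- img$foreground_mask[near(ry), near(rx), drop = FALSE]
  image_record(clamp(out), mask, img$species_id, img$specimen_id,
               img$domain, img$pose)
}
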