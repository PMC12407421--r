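# Shared fixtures, all built in code.

# Axis-aligned unit cube (12 triangles).
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = side
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = side
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6)    # x = side
  )
  tri_mesh(v, f, "cube")
}

# Regular tetrahedron.
tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
  tri_mesh(v, f, "tetra")
}

# Minimal fabricated image record.
toy_record <- function(side = 16, value = 0.5, domain = "synthetic",
                       species = "spA", specimen = "spA_i001") {
  pix <- array(value, dim = c(side, side, 3))
  mask <- matrix(FALSE, side, side)
  mask[(side / 4):(side / 2), (side / 4):(side / 2)] <- TRUE
  morphadapt:::image_record(pix, mask, species, specimen, domain)
}

# Manifest of n specimens per species, without rendering anything.
toy_manifest <- function(per_species, images_each = 1) {
  rows <- list()
  for (s in seq_along(per_species)) {
    for (k in seq_len(per_species[s])) {
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = sprintf("sp%02d_i%03d", s, k),
        species_id = sprintf("sp%02d", s),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df[rep(seq_len(nrow(df)), each = images_each), , drop = FALSE]
}

# Small rendered two-domain corpus + datasets, cached across tests.
desk_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_experiment_config("desk_test")
      cfg$log_level <- "quiet"
      cache <<- list(cfg = cfg, data = build_experiment_data(cfg))
    }
    cache
  }
})

# Fabricated two-class dataset: class A bright top-left block, class B bright
# bottom-right block, plus per-image noise. Learnable in a few epochs at 16 px.
clamp_arr <- function(a) {
  a[a > 1] <- 1
  a[a < 0] <- 0
  a
}
make_toy_ds <- function(n_per_class, side = 16, seed = 1, domain = "synthetic",
                        noise = 0.05, specimen_offset = 0) {
  recs <- list()
  set.seed(seed)
  for (cl in 1:2) {
    for (k in seq_len(n_per_class)) {
      pix <- array(stats::runif(side * side * 3, 0, noise),
                   dim = c(side, side, 3))
      block <- if (cl == 1) 1:(side / 2) else (side / 2 + 1):side
      pix[block, block, ] <- pix[block, block, ] + 0.8
      mask <- matrix(FALSE, side, side)
      mask[block, block] <- TRUE
      recs[[length(recs) + 1]] <- morphadapt:::image_record(
        clamp_arr(pix), mask, sprintf("sp%02d", cl),
        sprintf("sp%02d_i%03d", cl, k + specimen_offset), domain)
    }
  }
  as_image_dataset(recs)
}
toy_bundle <- function(seed = 1) {
  list(train_synthetic = make_toy_ds(8, seed = seed),
       train_photo = make_toy_ds(8, seed = seed + 50, domain = "photo",
                                 specimen_offset = 100),
       test_synthetic = make_toy_ds(4, seed = seed + 100,
                                    specimen_offset = 200),
       test_photo = make_toy_ds(4, seed = seed + 150, domain = "photo",
                                specimen_offset = 300))
}
dataset_size_ <- function(ds) length(ds$y)

# Brute-force double-loop silhouette oracle.
silhouette_oracle <- function(points, labels) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == l]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force double-loop MMD^2 oracle.
mmd2_oracle <- function(A, B, bandwidths, estimator = "biased") {
  k <- function(x, y) sum(exp(-sum((x - y)^2) / (2 * bandwidths^2)))
  m <- nrow(A)
  n <- nrow(B)
  kaa <- 0
  for (i in 1:m) for (j in 1:m) kaa <- kaa + k(A[i, ], A[j, ])
  kbb <- 0
  for (i in 1:n) for (j in 1:n) kbb <- kbb + k(B[i, ], B[j, ])
  kab <- 0
  for (i in 1:m) for (j in 1:n) kab <- kab + k(A[i, ], B[j, ])
  if (estimator == "biased") {
    kaa / m^2 + kbb / n^2 - 2 * kab / (m * n)
  } else {
    kaa_u <- 0
    for (i in 1:m) for (j in 1:m) if (i != j) kaa_u <- kaa_u + k(A[i, ], A[j, ])
    kbb_u <- 0
    for (i in 1:n) for (j in 1:n) if (i != j) kbb_u <- kbb_u + k(B[i, ], B[j, ])
    kaa_u / (m * (m - 1)) + kbb_u / (n * (n - 1)) - 2 * kab / (m * n)
  }
}
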