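# viewsphere: camera lattice, software rasterizer, simulated photograph domain.
#
# Conventions (the mesh forge and dataset manifests share these):
#   yaw 0 puts the camera on the +x axis; positive pitch is above the equator
#   (pitch +90 is the dorsal view). The camera looks at the mesh centroid from
#   distance = multiplier x bounding radius; up = world z, except at the poles
#   where up = world x to break the yaw singularity.

#' Camera pose on the view sphere
#'
#' @param yaw Degrees in `[0, 360)`.
#' @param pitch Degrees in `[-90, 90]`.
#' @param distance Positive multiple of the mesh bounding radius.
#' @return A `camera_pose` object.
#' @export
camera_pose <- function(yaw, pitch, distance = 3) {
  assert_that(pitch >= -90 && pitch <= 90, "pitch must be in [-90, 90]")
  assert_that(distance > 0, "distance must be positive")
  yaw <- yaw %% 360
  if (abs(pitch) == 90) yaw <- 0  # single pose at each pole
  structure(list(yaw = yaw, pitch = pitch, distance = distance),
            class = "camera_pose")
}

#' View-sphere lattice specification
#'
#' @param yaw_step Positive yaw increment in degrees; must divide 360.
#' @param ring_pitches Pitches of the yaw rings, strictly inside (-90, 90).
#' @param include_poles Add the two single pole views (pitch +-90).
#' @param distance Camera distance multiplier shared by all poses.
#' @return A `view_sphere_spec` object.
#' @export
view_sphere_spec <- function(yaw_step = 20,
                             ring_pitches = c(0, 30, -30, 60, -60),
                             include_poles = TRUE, distance = 3) {
  assert_that(yaw_step > 0 && 360 %% yaw_step == 0,
              "yaw_step must be a positive divisor of 360")
  assert_that(all(ring_pitches > -90 & ring_pitches < 90),
              "ring_pitches must be strictly inside (-90, 90)")
  assert_that(!anyDuplicated(ring_pitches), "ring_pitches must be distinct")
  structure(list(yaw_step = yaw_step, ring_pitches = ring_pitches,
                 include_poles = include_poles, distance = distance),
            class = "view_sphere_spec")
}

#' Enumerate the camera poses of a view-sphere lattice
#'
#' Pose count is `(360 / yaw_step) * length(ring_pitches) + 2 * include_poles`.
#' The default lattice (20 degree yaw steps on rings at 0, +-30, +-60 degrees
#' plus both poles) gives the 92-view scheme used for specimen digitisation.
#'
#' @param spec A [view_sphere_spec()].
#' @return List of [camera_pose()] in deterministic order: pitch descending,
#'   then yaw ascending.
#' @export
view_sphere_poses <- function(spec) {
  assert_that(inherits(spec, "view_sphere_spec"),
              "spec must be a view_sphere_spec")
  yaws <- seq(0, 360 - spec$yaw_step, by = spec$yaw_step)
  poses <- list()
  if (spec$include_poles) {
    poses[[1]] <- camera_pose(0, 90, spec$distance)
  }
  for (p in sort(spec$ring_pitches, decreasing = TRUE)) {
    for (y in yaws) {
      poses[[length(poses) + 1L]] <- camera_pose(y, p, spec$distance)
    }
  }
  if (spec$include_poles) {
    poses[[length(poses) + 1L]] <- camera_pose(0, -90, spec$distance)
  }
  poses
}

#' Renderer configuration
#'
#' @param resolution Square frame side in pixels (>= 16).
#' @param light_direction Direction toward the light (normalised internally).
#' @param ambient Ambient term in `[0, 1]`.
#' @param background_level Background gray level in `[0, 1]`.
#' @param fov Perspective field of view in degrees.
#' @param base_color RGB albedo of the shaded surface.
#' @return A `render_config` object.
#' @export
render_config <- function(resolution = 64,
                          light_direction = c(0.4, 0.3, 0.85),
                          ambient = 0.25, background_level = 0.12,
                          fov = 35, base_color = c(0.93, 0.90, 0.84)) {
  assert_that(resolution >= 16, "resolution must be at least 16")
  assert_that(ambient >= 0 && ambient <= 1, "ambient must be in [0, 1]")
  l <- light_direction / sqrt(sum(light_direction^2))
  structure(list(resolution = as.integer(resolution), light_direction = l,
                 ambient = ambient, background_level = background_level,
                 fov = fov, base_color = base_color),
            class = "render_config")
}

#' Photograph-domain nuisance configuration
#'
#' All effects vanish when every magnitude is zero, in which case the
#' photo-domain render equals the clean render pixel for pixel.
#'
#' @param background_marking_density Density of turntable-like radial marks
#'   behind the specimen (0 disables).
#' @param brightness_jitter_sd SD of the multiplicative brightness jitter.
#' @param color_cast_strength SD of per-channel multiplicative colour cast.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param noise_sd SD of additive pixel noise.
#' @param distance_jitter_sd SD of multiplicative camera-distance jitter.
#' @param session_confound Tie the background mark pattern to the specimen
#'   identity, creating a contextual clue a classifier can exploit instead of
#'   morphology.
#' @return A `photo_domain_config` object.
#' @export
photo_domain_config <- function(background_marking_density = 1,
                                brightness_jitter_sd = 0.15,
                                color_cast_strength = 0.12,
                                blur_sigma = 0.8,
                                noise_sd = 0.04,
                                distance_jitter_sd = 0.05,
                                session_confound = FALSE) {
  vals <- c(background_marking_density, brightness_jitter_sd,
            color_cast_strength, blur_sigma, noise_sd, distance_jitter_sd)
  assert_that(all(vals >= 0), "photo-domain magnitudes must be non-negative")
  structure(list(background_marking_density = background_marking_density,
                 brightness_jitter_sd = brightness_jitter_sd,
                 color_cast_strength = color_cast_strength,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 distance_jitter_sd = distance_jitter_sd,
                 session_confound = isTRUE(session_confound)),
            class = "photo_domain_config")
}

image_record <- function(pixels, foreground_mask, species_id = NA_character_,
                         specimen_id = NA_character_, domain = "synthetic",
                         pose = NULL) {
  structure(list(pixels = pixels, foreground_mask = foreground_mask,
                 species_id = species_id, specimen_id = specimen_id,
                 domain = domain, pose = pose),
            class = "image_record")
}

# Camera basis for a pose around a mesh: returns camera position and the
# world-to-camera rotation (rows: right, up, forward).
camera_basis <- function(mesh, pose) {
  centroid <- colMeans(mesh$vertices)
  radius <- max(sqrt(rowSums(sweep(mesh$vertices, 2, centroid)^2)))
  yaw <- pose$yaw * pi / 180
  pitch <- pose$pitch * pi / 180
  dir <- c(cos(pitch) * cos(yaw), cos(pitch) * sin(yaw), sin(pitch))
  cam <- centroid + dir * pose$distance * radius
  fwd <- -dir
  up_hint <- if (abs(pose$pitch) >= 89.999) c(1, 0, 0) else c(0, 0, 1)
  right <- c(fwd[2] * up_hint[3] - fwd[3] * up_hint[2],
             fwd[3] * up_hint[1] - fwd[1] * up_hint[3],
             fwd[1] * up_hint[2] - fwd[2] * up_hint[1])
  right <- right / sqrt(sum(right^2))
  up <- c(right[2] * fwd[3] - right[3] * fwd[2],
          right[3] * fwd[1] - right[1] * fwd[3],
          right[1] * fwd[2] - right[2] * fwd[1])
  list(cam = cam, rot = rbind(right, up, fwd), radius = radius)
}

#' Render a mesh from a camera pose (clean synthetic domain)
#'
#' Perspective projection, z-buffered triangle rasterization and flat
#' Lambertian shading (ambient + diffuse with the triangle normal oriented
#' toward the camera; no back-face culling, no shadows). Fully deterministic.
#'
#' @param mesh A [tri_mesh()].
#' @param pose A [camera_pose()].
#' @param cfg A [render_config()].
#' @param species_id,specimen_id Labels carried into the record.
#' @return An `image_record` with pixels in `[0, 1]`, a logical foreground
#'   mask, and domain tag `"synthetic"`.
#' @export
render <- function(mesh, pose, cfg = render_config(),
                   species_id = NA_character_, specimen_id = NA_character_) {
  assert_that(is_tri_mesh(mesh), "mesh must be a tri_mesh")
  assert_that(inherits(pose, "camera_pose"), "pose must be a camera_pose")
  res <- cfg$resolution
  cb <- camera_basis(mesh, pose)
  vc <- sweep(mesh$vertices, 2, cb$cam) %*% t(cb$rot)  # camera coords
  z <- vc[, 3]
  if (all(z <= 1e-9)) stop("degenerate view: mesh entirely behind camera")

  f <- 1 / tan(cfg$fov * pi / 360)
  px <- (vc[, 1] / z * f + 1) / 2 * res  # continuous pixel coords
  py <- (1 - vc[, 2] / z * f) / 2 * res

  pix <- array(cfg$background_level, dim = c(res, res, 3))
  zbuf <- matrix(Inf, res, res)
  shade <- matrix(NA_real_, res, res)
  mask <- matrix(FALSE, res, res)

  l <- cfg$light_direction
  fc <- mesh$faces
  for (t in seq_len(nrow(fc))) {
    i <- fc[t, ]
    if (any(z[i] <= 1e-9)) next
    x0 <- px[i[1]]; x1 <- px[i[2]]; x2 <- px[i[3]]
    y0 <- py[i[1]]; y1 <- py[i[2]]; y2 <- py[i[3]]
    area <- (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0)
    if (abs(area) < 1e-12) next
    cmin <- max(1L, floor(min(x0, x1, x2) + 0.5))
    cmax <- min(res, ceiling(max(x0, x1, x2) + 0.5))
    rmin <- max(1L, floor(min(y0, y1, y2) + 0.5))
    rmax <- min(res, ceiling(max(y0, y1, y2) + 0.5))
    if (cmin > cmax || rmin > rmax) next
    cx <- (cmin:cmax) - 0.5
    cy <- (rmin:rmax) - 0.5
    X <- matrix(cx, length(cy), length(cx), byrow = TRUE)
    Y <- matrix(cy, length(cy), length(cx))
    w0 <- ((x1 - x0) * (Y - y0) - (y1 - y0) * (X - x0)) / area
    w1 <- ((x2 - x1) * (Y - y1) - (y2 - y1) * (X - x1)) / area
    w2 <- ((x0 - x2) * (Y - y2) - (y0 - y2) * (X - x2)) / area
    inside <- (w0 >= 0 & w1 >= 0 & w2 >= 0)
    if (!any(inside)) next
    depth <- w1 * z[i[1]] + w2 * z[i[2]] + w0 * z[i[3]]

    # world-space flat shading, normal flipped toward the camera
    a <- mesh$vertices[i[2], ] - mesh$vertices[i[1], ]
    b <- mesh$vertices[i[3], ] - mesh$vertices[i[1], ]
    n <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    nn <- sqrt(sum(n^2))
    if (nn < 1e-15) next
    n <- n / nn
    to_cam <- cb$cam - colMeans(mesh$vertices[i, , drop = FALSE])
    if (sum(n * to_cam) < 0) n <- -n
    intensity <- clamp(cfg$ambient + (1 - cfg$ambient) * max(0, sum(n * l)))

    rows <- rmin:rmax
    cols <- cmin:cmax
    sub_z <- zbuf[rows, cols, drop = FALSE]
    upd <- inside & (depth < sub_z)
    if (!any(upd)) next
    sub_z[upd] <- depth[upd]
    zbuf[rows, cols] <- sub_z
    sub_s <- shade[rows, cols, drop = FALSE]
    sub_s[upd] <- intensity
    shade[rows, cols] <- sub_s
    sub_m <- mask[rows, cols, drop = FALSE]
    sub_m[upd] <- TRUE
    mask[rows, cols] <- sub_m
  }

  for (ch in 1:3) {
    plane <- pix[, , ch]
    plane[mask] <- shade[mask] * cfg$base_color[ch]
    pix[, , ch] <- plane
  }
  image_record(clamp(pix), mask, species_id, specimen_id, "synthetic", pose)
}

# Turntable-like background: radial marks around the frame centre, drawn on
# the uniform backdrop. With the session confound, the mark count and phase
# are keyed to the specimen identity.
marked_background <- function(res, cfg, pd, specimen_id) {
  bg <- array(cfg$background_level, dim = c(res, res, 3))
  if (pd$background_marking_density <= 0) return(bg)
  n_marks <- max(1, round(12 * pd$background_marking_density))
  phase <- 0
  if (pd$session_confound && !is.na(specimen_id)) {
    h <- string_hash(specimen_id)
    n_marks <- n_marks + h %% 7L
    phase <- (h %% 360L) * pi / 180
  }
  cx <- (res + 1) / 2
  xs <- matrix(seq_len(res) - cx, res, res, byrow = TRUE)
  ys <- matrix(seq_len(res) - cx, res, res)
  theta <- atan2(ys, xs)
  r <- sqrt(xs^2 + ys^2) / res
  ang <- ((theta + phase) / (2 * pi)) * n_marks
  on_mark <- (abs(ang - round(ang)) < 0.035) & r > 0.28 & r < 0.49
  level <- clamp(cfg$background_level + 0.45)
  for (ch in 1:3) {
    plane <- bg[, , ch]
    plane[on_mark] <- level
    bg[, , ch] <- plane
  }
  bg
}

# Separable Gaussian blur, edge-replicated.
gaussian_blur <- function(pix, sigma) {
  if (sigma <= 0) return(pix)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1d <- function(m, along) {
    n <- if (along == 1) nrow(m) else ncol(m)
    out <- m * 0
    for (o in (-rad):rad) {
      idx <- clamp(seq_len(n) + o, 1, n)
      shifted <- if (along == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
      out <- out + k[o + rad + 1] * shifted
    }
    out
  }
  for (ch in 1:3) {
    pix[, , ch] <- blur1d(blur1d(pix[, , ch], 1), 2)
  }
  pix
}

#' Render a mesh into the simulated photograph domain
#'
#' Renders the mesh (with optional camera-distance jitter), composites the
#' backdrop with turntable-like radial markings, then applies brightness
#' jitter, a per-channel colour cast, Gaussian blur and additive noise.
#' Deterministic given the seed; with every magnitude zero the output equals
#' [render()] exactly.
#'
#' @inheritParams render
#' @param pd A [photo_domain_config()].
#' @param rng_seed Integer seed for the nuisance draws.
#' @return An `image_record` with domain tag `"photo"`.
#' @export
render_photo_domain <- function(mesh, pose, cfg = render_config(),
                                pd = photo_domain_config(), rng_seed = 1,
                                species_id = NA_character_,
                                specimen_id = NA_character_) {
  assert_that(inherits(pd, "photo_domain_config"),
              "pd must be a photo_domain_config")
  with_seed(rng_seed, {
    dj <- stats::rnorm(1) * pd$distance_jitter_sd
    pose2 <- camera_pose(pose$yaw, pose$pitch,
                         pose$distance * max(0.2, 1 + dj))
    rec <- render(mesh, pose2, cfg, species_id, specimen_id)
    pix <- rec$pixels
    res <- cfg$resolution

    bg <- marked_background(res, cfg, pd, specimen_id)
    for (ch in 1:3) {
      plane <- pix[, , ch]
      bgp <- bg[, , ch]
      plane[!rec$foreground_mask] <- bgp[!rec$foreground_mask]
      pix[, , ch] <- plane
    }

    bright <- 1 + stats::rnorm(1) * pd$brightness_jitter_sd
    cast <- 1 + stats::rnorm(3) * pd$color_cast_strength
    for (ch in 1:3) pix[, , ch] <- pix[, , ch] * bright * cast[ch]

    pix <- gaussian_blur(pix, pd$blur_sigma)
    if (pd$noise_sd > 0) {
      pix <- pix + array(stats::rnorm(length(pix)), dim = dim(pix)) * pd$noise_sd
    }
    image_record(clamp(pix), rec$foreground_mask, species_id, specimen_id,
                 "photo", pose2)
  })
}

#' Render a specimen bank over a view-sphere lattice
#'
#' One image per specimen-pose pair, in either the clean synthetic domain or
#' (when `pd` is supplied) the simulated photograph domain. With
#' `render = FALSE` only the task manifest is produced, which is how the
#' full-scale render workload (e.g. 479 assets x 92 poses = 44,068 tasks) is
#' enumerated without rasterizing.
#'
#' @param bank Output of [generate_species_bank()].
#' @param spec A [view_sphere_spec()].
#' @param cfg A [render_config()].
#' @param pd Optional [photo_domain_config()]; its presence selects the photo
#'   domain.
#' @param seed Master seed for photo-domain nuisance draws.
#' @param render Rasterize images (`TRUE`) or emit the manifest only.
#' @param out_dir Optional directory; when given, images are also written as
#'   8-bit RGB PNGs and the manifest gains their paths.
#' @return `list(records =, manifest =)`; `records` is `NULL` when
#'   `render = FALSE`. The manifest has one row per task with columns
#'   specimen_id, species_id, yaw, pitch, domain, path.
#' @export
render_dataset <- function(bank, spec, cfg = render_config(), pd = NULL,
                           seed = 1, render = TRUE, out_dir = NULL) {
  assert_that(length(bank) > 0, "bank must be nonempty")
  poses <- view_sphere_poses(spec)
  domain <- if (is.null(pd)) "synthetic" else "photo"
  n <- length(bank) * length(poses)
  manifest <- data.frame(
    specimen_id = rep(vapply(bank, `[[`, character(1), "specimen_id"),
                      each = length(poses)),
    species_id = rep(vapply(bank, `[[`, character(1), "species_id"),
                     each = length(poses)),
    yaw = rep(vapply(poses, `[[`, numeric(1), "yaw"), length(bank)),
    pitch = rep(vapply(poses, `[[`, numeric(1), "pitch"), length(bank)),
    domain = rep(domain, n),
    path = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (!render) return(list(records = NULL, manifest = manifest))

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  records <- vector("list", n)
  row <- 0L
  for (b in seq_along(bank)) {
    sp <- bank[[b]]
    for (k in seq_along(poses)) {
      row <- row + 1L
      rec <- tryCatch({
        if (is.null(pd)) {
          render(sp$mesh, poses[[k]], cfg, sp$species_id, sp$specimen_id)
        } else {
          render_photo_domain(sp$mesh, poses[[k]], cfg, pd,
                              rng_seed = derive_seed(seed, b, k),
                              species_id = sp$species_id,
                              specimen_id = sp$specimen_id)
        }
      }, error = function(e) {
        stop("render failed for specimen ", sp$specimen_id, ": ",
             conditionMessage(e))
      })
      if (!is.null(out_dir)) {
        fn <- file.path(out_dir, sprintf("%s_y%03d_p%+03d_%s.png",
                                         sp$specimen_id, round(rec$pose$yaw),
                                         round(rec$pose$pitch), domain))
        png::writePNG(rec$pixels, fn)
        manifest$path[row] <- fn
      }
      records[[row]] <- rec
    }
  }
  list(records = records, manifest = manifest)
}
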