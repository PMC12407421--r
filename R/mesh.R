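# meshforge: procedural specimen meshes, standardisation, decimation, OBJ I/O.
#
# The anterior-posterior axis of every forge mesh is the local x axis
# (configurable in the standardisation ops). Shape family: a superellipsoid
# body deformed by a rostrum taper toward +x, a dorsal sagittal-crest ridge,
# and two ventro-lateral bump arcs standing in for tooth rows. A handful of
# parameters yields classes that are visually distinct from most view angles.

#' Construct a triangle mesh
#'
#' @param vertices Numeric matrix, one row per vertex, three columns (x, y, z).
#' @param faces Integer matrix, one row per triangle, three 1-based vertex
#'   indices per row.
#' @param name Text identifier.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  assert_that(ncol(vertices) == 3, "vertices must have 3 columns")
  assert_that(nrow(vertices) >= 4, "a solid mesh needs at least 4 vertices")
  assert_that(nrow(faces) >= 4, "a solid mesh needs at least 4 faces")
  assert_that(all(is.finite(vertices)), "vertex coordinates must be finite")
  assert_that(all(faces >= 1) && all(faces <= nrow(vertices)),
              "face indices must reference existing vertices")
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

is_tri_mesh <- function(x) inherits(x, "tri_mesh")

# Names and plausible ranges of the forge's morphology parameters.
# length/width/height are semi-axes of the body; exponents shape the
# superellipsoid cross-sections; the rest drive the deformations.
forge_param_ranges <- function() {
  rbind(
    length      = c(0.8, 1.6),
    width       = c(0.35, 0.75),
    height      = c(0.30, 0.65),
    exp_lat     = c(0.6, 1.6),   # latitude exponent
    exp_lon     = c(0.6, 1.6),   # longitude exponent
    taper       = c(0.25, 0.85), # rostrum cross-section shrink factor at +x tip
    crest_amp   = c(0.0, 0.35),  # sagittal crest height
    crest_width = c(0.10, 0.30), # crest gaussian width (fraction of length)
    bump_amp    = c(0.0, 0.12),  # tooth-row bump amplitude
    bump_freq   = c(2, 7)        # bump rows along each lateral arc
  )
}

#' Species morphology specification
#'
#' @param species_id Text identifier.
#' @param base_shape_params Named numeric vector of morphology parameters
#'   (see `forge_param_ranges()` for names and plausible ranges).
#' @param within_species_sd Per-parameter standard deviation of specimen-level
#'   Gaussian perturbation (non-negative, recycled to parameter length).
#' @param base_length Anterior-posterior extent in scene units.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(species_id, base_shape_params,
                         within_species_sd = 0.02, base_length = 1) {
  p <- base_shape_params
  rng <- forge_param_ranges()
  assert_that(!is.null(names(p)) && all(rownames(rng) %in% names(p)),
              "base_shape_params must be named and cover all forge parameters")
  sd <- rep_len(within_species_sd, length(p))
  names(sd) <- names(p)
  assert_that(all(sd >= 0), "within_species_sd must be non-negative")
  assert_that(base_length > 0, "base_length must be positive")
  structure(list(species_id = as.character(species_id),
                 base_shape_params = p,
                 within_species_sd = sd,
                 base_length = base_length),
            class = "species_spec")
}

# Signed power that keeps superellipsoid surfaces well defined.
spow <- function(x, e) sign(x) * abs(x)^e

# Build the deformed-superellipsoid surface for one parameter vector.
# Grid resolution (n_u latitudes x n_v longitudes) is fixed so a specimen is
# always a closed solid with 2 * (n_u - 1) * n_v triangles.
forge_surface <- function(p, n_u = 17, n_v = 24) {
  u <- seq(-pi / 2, pi / 2, length.out = n_u)        # latitude, poles at ends
  v <- seq(0, 2 * pi, length.out = n_v + 1)[-(n_v + 1)]
  U <- matrix(u, n_u, n_v)
  V <- matrix(v, n_u, n_v, byrow = TRUE)

  cu <- spow(cos(U), p["exp_lat"])
  su <- spow(sin(U), p["exp_lat"])
  cv <- spow(cos(V), p["exp_lon"])
  sv <- spow(sin(V), p["exp_lon"])

  x <- p["length"] * cu * cv
  y <- p["width"] * cu * sv
  z <- p["height"] * su

  # Rostrum taper: shrink the y/z cross-section linearly toward the +x tip.
  tfrac <- clamp((x / p["length"] + 1) / 2, 0, 1)   # 0 at -x pole, 1 at +x tip
  shrink <- 1 - (1 - p["taper"]) * tfrac
  y <- y * shrink
  z <- z * shrink

  # Sagittal crest: gaussian ridge along the dorsal midline, centred at the
  # posterior third (braincase), widest at y = 0.
  xc <- -0.3 * p["length"]
  ridge <- p["crest_amp"] *
    exp(-((x - xc) / (p["crest_width"] * 2 * p["length"]))^2) *
    exp(-(y / (0.15 * p["width"]))^2)
  z <- z + ridge * (z > 0)

  # Tooth-row analogue: sinusoidal bumps along two ventro-lateral arcs on the
  # anterior half.
  lat_sel <- (z < 0) & (abs(y) > 0.3 * p["width"]) & (x > 0)
  bumps <- p["bump_amp"] * abs(sin(p["bump_freq"] * pi * x / p["length"]))
  z <- z - bumps * lat_sel

  # Collapse duplicate pole rows into single vertices.
  verts <- cbind(as.vector(x), as.vector(y), as.vector(z))
  idx <- matrix(seq_len(n_u * n_v), n_u, n_v)       # column-major: u fastest
  south <- colMeans(verts[idx[1, ], , drop = FALSE])
  north <- colMeans(verts[idx[n_u, ], , drop = FALSE])
  body_rows <- as.vector(idx[2:(n_u - 1), ])
  remap <- integer(n_u * n_v)
  remap[body_rows] <- seq_along(body_rows) + 2L
  vertices <- rbind(south, north, verts[body_rows, , drop = FALSE])
  rownames(vertices) <- NULL

  faces <- list()
  ring <- function(i, j) remap[idx[i, (j - 1) %% n_v + 1]]
  # pole fans
  f_south <- cbind(1L, sapply(1:n_v, function(j) ring(2, j + 1)),
                   sapply(1:n_v, function(j) ring(2, j)))
  f_north <- cbind(2L, sapply(1:n_v, function(j) ring(n_u - 1, j)),
                   sapply(1:n_v, function(j) ring(n_u - 1, j + 1)))
  # quad strips
  quads <- expand.grid(i = 2:(n_u - 2), j = 1:n_v)
  a <- mapply(ring, quads$i, quads$j)
  b <- mapply(ring, quads$i + 1, quads$j)
  cc <- mapply(ring, quads$i + 1, quads$j + 1)
  d <- mapply(ring, quads$i, quads$j + 1)
  faces <- rbind(f_south, f_north, cbind(a, b, cc), cbind(a, cc, d))
  tri_mesh(vertices, faces)
}

#' Generate one specimen mesh from a species specification
#'
#' Specimen-level variation is an independent Gaussian perturbation of each
#' morphology parameter, scaled by `within_species_sd` and clamped to the
#' forge's plausible ranges. The same `(spec, specimen_seed)` pair always
#' yields an identical mesh.
#'
#' @param spec A [species_spec()].
#' @param specimen_seed Integer seed for the perturbation.
#' @return A [tri_mesh()], standardised to `spec$base_length` along x and
#'   centred at the origin.
#' @export
generate_specimen <- function(spec, specimen_seed) {
  assert_that(inherits(spec, "species_spec"), "spec must be a species_spec")
  rng <- forge_param_ranges()
  p <- with_seed(specimen_seed, {
    spec$base_shape_params +
      stats::rnorm(length(spec$base_shape_params)) * spec$within_species_sd
  })
  p <- pmin(pmax(p, rng[names(p), 1]), rng[names(p), 2])
  mesh <- forge_surface(p)
  mesh$name <- spec$species_id
  standardize_length(mesh, target_length = spec$base_length, axis = 1)
}

#' Generate a bank of procedurally varied specimens
#'
#' Species base parameters are drawn from the forge ranges under the master
#' seed, with rejection sampling enforcing a minimum inter-species distance
#' (in units of the within-species standard deviation) so species are
#' separable by construction.
#'
#' @param n_species Number of species classes (>= 2).
#' @param specimens_per_species Specimens forged per species (>= 2).
#' @param seed Master seed; the bank is a pure function of the arguments.
#' @param drop Optional list of `c(species_index, count)` pairs removing
#'   specimens from the end of a species' roster (emulating corrupted scans).
#' @param within_species_sd Per-parameter specimen perturbation SD.
#' @param separation Minimum inter-species distance in normalised parameter
#'   space, as a multiple of `within_species_sd`.
#' @return A list of specimen records, each `list(specimen_id, species_id,
#'   mesh, seed)`, with attribute `"species"` holding the species_spec list.
#' @export
generate_species_bank <- function(n_species, specimens_per_species, seed = 1,
                                  drop = NULL, within_species_sd = 0.02,
                                  separation = 8) {
  assert_that(n_species >= 2, "n_species must be at least 2")
  assert_that(specimens_per_species >= 2,
              "specimens_per_species must be at least 2")
  if (!is.null(drop)) {
    for (d in drop) {
      assert_that(length(d) == 2 && d[1] >= 1 && d[1] <= n_species,
                  "drop entries must be c(species_index, count)")
      assert_that(d[2] < specimens_per_species,
                  "cannot drop all specimens of a species")
    }
  }
  rng <- forge_param_ranges()
  span <- rng[, 2] - rng[, 1]

  species <- with_seed(seed, {
    bases <- list()
    min_dist <- separation * within_species_sd * sqrt(nrow(rng))
    for (s in seq_len(n_species)) {
      repeat {
        cand <- rng[, 1] + stats::runif(nrow(rng)) * span
        names(cand) <- rownames(rng)
        ok <- all(vapply(bases, function(b) {
          sqrt(sum(((cand - b) / span)^2)) >= min_dist
        }, logical(1)))
        if (ok) break
      }
      bases[[s]] <- cand
    }
    lapply(seq_len(n_species), function(s) {
      species_spec(sprintf("sp%02d", s), bases[[s]],
                   within_species_sd = within_species_sd * span)
    })
  })

  drop_n <- integer(n_species)
  if (!is.null(drop)) for (d in drop) drop_n[d[1]] <- drop_n[d[1]] + d[2]

  bank <- list()
  for (s in seq_len(n_species)) {
    keep <- specimens_per_species - drop_n[s]
    for (k in seq_len(keep)) {
      sseed <- derive_seed(seed, s, k)
      bank[[length(bank) + 1L]] <- list(
        specimen_id = sprintf("sp%02d_i%03d", s, k),
        species_id = species[[s]]$species_id,
        mesh = generate_specimen(species[[s]], sseed),
        seed = sseed
      )
    }
  }
  attr(bank, "species") <- species
  bank
}

#' Forge manifest as a data frame
#'
#' @param bank Output of [generate_species_bank()].
#' @return Data frame with columns specimen_id, species_id, seed.
#' @export
bank_manifest <- function(bank) {
  data.frame(
    specimen_id = vapply(bank, `[[`, character(1), "specimen_id"),
    species_id = vapply(bank, `[[`, character(1), "species_id"),
    seed = vapply(bank, `[[`, integer(1), "seed"),
    stringsAsFactors = FALSE
  )
}

#' Scale a mesh to a standardised length along one axis
#'
#' Applies a uniform scale so the bounding-box extent along `axis` equals
#' `target_length`, then translates the vertex centroid to the origin.
#' Idempotent and invariant to any uniform pre-scaling of the input.
#'
#' @param mesh A [tri_mesh()].
#' @param target_length Positive target extent.
#' @param axis Axis index (1 = x, the anterior-posterior convention).
#' @return The standardised [tri_mesh()].
#' @export
standardize_length <- function(mesh, target_length, axis = 1) {
  assert_that(is_tri_mesh(mesh), "mesh must be a tri_mesh")
  assert_that(target_length > 0, "target_length must be positive")
  ext <- diff(range(mesh$vertices[, axis]))
  if (ext <= 0) {
    stop("degenerate mesh: zero extent along axis ", axis)
  }
  v <- mesh$vertices * (target_length / ext)
  v <- sweep(v, 2, colMeans(v))
  tri_mesh(v, mesh$faces, mesh$name)
}

#' Decimate a mesh to a face budget by vertex clustering
#'
#' Vertices are clustered on a uniform grid over the bounding box; each
#' cluster is replaced by the mean of its members and degenerate/duplicate
#' faces are dropped. The grid resolution is chosen (by bisection) as the
#' finest that meets the face budget. Meshes already within budget are
#' returned unchanged.
#'
#' @param mesh A [tri_mesh()].
#' @param target_faces Face budget (>= 4).
#' @return A [tri_mesh()] with at most `target_faces` faces.
#' @export
decimate <- function(mesh, target_faces) {
  assert_that(is_tri_mesh(mesh), "mesh must be a tri_mesh")
  assert_that(target_faces >= 4, "target_faces must be at least 4")
  if (nrow(mesh$faces) <= target_faces) return(mesh)

  cluster_once <- function(n_cells) {
    v <- mesh$vertices
    lo <- apply(v, 2, min)
    hi <- apply(v, 2, max)
    spanv <- pmax(hi - lo, 1e-12)
    cell <- pmin(floor((sweep(sweep(v, 2, lo), 2, spanv, "/")) * n_cells),
                 n_cells - 1)
    key <- cell[, 1] * n_cells^2 + cell[, 2] * n_cells + cell[, 3]
    grp <- match(key, unique(key))
    counts <- as.vector(rowsum(rep(1, nrow(v)), grp))
    nv <- rowsum(v, grp) / counts
    f <- matrix(grp[mesh$faces], ncol = 3)
    keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[keep, , drop = FALSE]
    if (nrow(f) > 0) {
      canon <- t(apply(f, 1, sort))
      f <- f[!duplicated(canon), , drop = FALSE]
    }
    list(vertices = nv, faces = f)
  }

  # finest grid whose clustered face count fits the budget
  lo_n <- 1L
  hi_n <- 64L
  best <- NULL
  while (lo_n <= hi_n) {
    mid <- (lo_n + hi_n) %/% 2L
    res <- cluster_once(mid)
    if (nrow(res$faces) <= target_faces) {
      if (nrow(res$faces) >= 4) best <- res
      lo_n <- mid + 1L
    } else {
      hi_n <- mid - 1L
    }
  }
  if (is.null(best)) {
    stop("decimation cannot reach a valid mesh within the face budget")
  }
  tri_mesh(best$vertices, best$faces, mesh$name)
}

#' Read a Wavefront OBJ file as a triangle mesh
#'
#' Parses `v` and `f` records; normals, texture coordinates and materials are
#' ignored. Negative (relative) face indices are resolved against the
#' vertices defined so far, per the OBJ standard. Polygonal faces are
#' fan-triangulated.
#'
#' @param path Path to an OBJ file.
#' @return A [tri_mesh()].
#' @export
read_obj <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  verts <- list()
  faces <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (tok[1] == "v") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4 || anyNA(xyz)) {
        stop("OBJ parse error at line ", ln, ": malformed vertex record")
      }
      verts[[length(verts) + 1L]] <- xyz
    } else if (tok[1] == "f") {
      if (length(tok) < 4) {
        stop("OBJ parse error at line ", ln, ": face needs >= 3 vertices")
      }
      raw <- vapply(tok[-1], function(t) {
        suppressWarnings(as.integer(strsplit(t, "/")[[1]][1]))
      }, integer(1))
      if (anyNA(raw) || any(raw == 0)) {
        stop("OBJ parse error at line ", ln, ": malformed face index")
      }
      nvert <- length(verts)
      idx <- ifelse(raw < 0, nvert + raw + 1L, raw)
      if (any(idx < 1) || any(idx > nvert)) {
        stop("OBJ parse error at line ", ln,
             ": face index out of range (", max(raw), " of ", nvert, ")")
      }
      for (k in 2:(length(idx) - 1)) {
        faces[[length(faces) + 1L]] <- c(idx[1], idx[k], idx[k + 1])
      }
    }
  }
  tri_mesh(do.call(rbind, verts), do.call(rbind, faces),
           name = sub("\\.obj$", "", basename(path), ignore.case = TRUE))
}

#' Write a triangle mesh as a Wavefront OBJ file
#'
#' Coordinates are printed with enough significant digits that a
#' write-then-read round trip reproduces them exactly.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_obj <- function(mesh, path) {
  assert_that(is_tri_mesh(mesh), "mesh must be a tri_mesh")
  v <- sprintf("v %.17g %.17g %.17g",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d",
               mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c(sprintf("# %s", mesh$name), v, f), path)
  invisible(path)
}
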