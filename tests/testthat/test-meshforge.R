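test_that("species bank has the expected size, layout and determinism", {
  b <- generate_species_bank(3, 4, seed = 1)
  expect_length(b, 12)
  man <- bank_manifest(b)
  expect_equal(as.vector(table(man$species_id)), rep(4L, 3))
  expect_false(anyDuplicated(man$specimen_id) > 0)

  # dropped specimens shrink exactly one species
  bd <- generate_species_bank(3, 4, seed = 1, drop = list(c(2, 1)))
  expect_length(bd, 11)
  expect_equal(sum(bank_manifest(bd)$species_id == "sp02"), 3L)

  # pure function of the seed
  b1 <- generate_species_bank(2, 2, seed = 0)
  b2 <- generate_species_bank(2, 2, seed = 0)
  expect_identical(b1[[1]]$mesh$vertices, b2[[1]]$mesh$vertices)
  expect_identical(b1[[4]]$mesh$vertices, b2[[4]]$mesh$vertices)

  expect_error(generate_species_bank(1, 5), "n_species")
  expect_error(generate_species_bank(2, 1), "specimens_per_species")
  expect_error(generate_species_bank(2, 3, drop = list(c(1, 3))), "drop")
})

test_that("specimen generation is seeded and species are separable", {
  rng <- morphadapt:::forge_param_ranges()
  base <- rng[, 1] + 0.5 * (rng[, 2] - rng[, 1])
  names(base) <- rownames(rng)
  sp <- species_spec("a", base, within_species_sd = 0.01)

  m1 <- generate_specimen(sp, 5)
  m2 <- generate_specimen(sp, 5)
  expect_identical(m1$vertices, m2$vertices)

  # zero variance: every specimen identical
  sp0 <- species_spec("a", base, within_species_sd = 0)
  expect_identical(generate_specimen(sp0, 1)$vertices,
                   generate_specimen(sp0, 2)$vertices)

  # widely separated base params -> inter-species distance beats within
  base_b <- base
  shift <- 0.1 * (rng[, 2] - rng[, 1])
  base_b[] <- pmin(base + shift, rng[, 2])
  sp_b <- species_spec("b", base_b, within_species_sd = 0.01)
  ma <- lapply(1:5, function(k) generate_specimen(sp, k)$vertices)
  mb <- lapply(1:5, function(k) generate_specimen(sp_b, k)$vertices)
  vdist <- function(x, y) mean(sqrt(rowSums((x - y)^2)))
  within <- mean(c(
    unlist(lapply(combn(5, 2, simplify = FALSE),
                  function(p) vdist(ma[[p[1]]], ma[[p[2]]]))),
    unlist(lapply(combn(5, 2, simplify = FALSE),
                  function(p) vdist(mb[[p[1]]], mb[[p[2]]])))))
  between <- mean(unlist(lapply(1:5, function(i)
    lapply(1:5, function(j) vdist(ma[[i]], mb[[j]])))))
  expect_gt(between, within)
})

test_that("default forge banks are 100% separable by nearest centroid", {
  b <- generate_species_bank(4, 5, seed = 3)
  feats <- t(vapply(b, function(r) as.vector(r$mesh$vertices),
                    numeric(length(as.vector(b[[1]]$mesh$vertices)))))
  labs <- vapply(b, `[[`, character(1), "species_id")
  cents <- do.call(rbind, lapply(unique(labs), function(l)
    colMeans(feats[labs == l, , drop = FALSE])))
  pred <- unique(labs)[apply(feats, 1, function(f)
    which.min(colSums((t(cents) - f)^2)))]
  expect_equal(pred, labs)
})

test_that("length standardisation scales, centres, and is idempotent", {
  m <- standardize_length(cube_mesh(), target_length = 2, axis = 1)
  expect_equal(diff(range(m$vertices[, 1])), 2, tolerance = 1e-12)
  expect_equal(unname(colMeans(m$vertices)), c(0, 0, 0), tolerance = 1e-12)

  m2 <- standardize_length(m, 2, axis = 1)
  expect_equal(m$vertices, m2$vertices, tolerance = 1e-12)

  # scale-equivariance: a uniformly pre-scaled mesh standardises identically
  pre <- cube_mesh()
  pre$vertices <- pre$vertices * 7.3
  expect_equal(standardize_length(pre, 2, axis = 1)$vertices,
               standardize_length(cube_mesh(), 2, axis = 1)$vertices,
               tolerance = 1e-9)

  flat <- tri_mesh(cbind(0, c(0, 1, 0, 1), c(0, 0, 1, 1)),
                   rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 2), c(2, 3, 4)))
  expect_error(standardize_length(flat, 1, axis = 1), "degenerate")
})

test_that("decimation respects the face budget and mesh validity", {
  m <- cube_mesh()  # 12 faces
  expect_identical(decimate(m, 200), m)  # no-op branch

  big <- generate_specimen(
    species_spec("a", {
      rng <- morphadapt:::forge_param_ranges()
      p <- rng[, 1] + 0.5 * (rng[, 2] - rng[, 1])
      names(p) <- rownames(rng)
      p
    }, within_species_sd = 0), 1)
  expect_gt(nrow(big$faces), 320)
  d <- decimate(big, 320)
  expect_lte(nrow(d$faces), 320)
  expect_gte(nrow(d$faces), 4)
  expect_true(all(d$faces >= 1 & d$faces <= nrow(d$vertices)))
  expect_true(all(is.finite(d$vertices)))
  expect_error(decimate(big, 3), "target_faces")
})

test_that("OBJ files round-trip and malformed input is rejected", {
  path <- withr::local_tempfile(fileext = ".obj")
  m <- tetra_mesh()
  m$vertices[1, ] <- c(0.123456789012345, -7.5e-4, 1 / 3)
  write_obj(m, path)
  back <- read_obj(path)
  expect_identical(back$faces, m$faces)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-15)

  # relative (negative) indices resolve against vertices defined so far
  rel <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f -4 -3 -2", "f 1 3 4", "f -4 -1 -2", "f 2 4 3"), rel)
  mr <- read_obj(rel)
  expect_equal(mr$faces[1, ], c(1L, 2L, 3L))
  expect_equal(mr$faces[3, ], c(1L, 4L, 3L))

  bad <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1", "f 1 2 99"), bad)
  expect_error(read_obj(bad), "line 5")

  bad2 <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2"), bad2)
  expect_error(read_obj(bad2), "line 4")

  # texture/normal face syntax is accepted, extra records ignored
  tex <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "vn 0 0 1", "vt 0 0",
               "f 1/1/1 2/1/1 3/1/1", "f 1 3 4", "f 1 4 2", "f 2 4 3"), tex)
  expect_equal(nrow(read_obj(tex)$faces), 4)
})
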