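test_that("spec defaults equal the built-in typical dimensions", {
  dims <- vertebra_dimensions()
  for (i in seq_len(nrow(dims))) {
    sp <- vertebra_spec(dims$level[i])
    expect_equal(c(sp$height, sp$width, sp$length),
                 c(dims$height[i], dims$width[i], dims$length[i]))
  }
  expect_error(vertebra_spec("T1"), "unknown")
  expect_error(vertebra_spec("C5", height = -1), "positive")
  expect_error(vertebra_spec("C5", remesh_factor = 5), "remesh_factor")
})

test_that("generated vertebrae are valid and sized to the constants", {
  dims <- vertebra_dimensions()
  for (lev in dims$level) {
    m <- generate_vertebra(vertebra_spec(lev, subdivisions = 3L))
    expect_true(is_closed_mesh(m), info = lev)
    bb <- mesh_bbox(m)
    ext <- bb[, 2] - bb[, 1]
    i <- match(lev, dims$level)
    want <- c(dims$width[i], dims$height[i], dims$length[i])
    expect_lt(max(abs(ext - want) / want), 0.02, label = lev)
  }
  # asymmetry: no mirror symmetry about the mid-sagittal plane
  m <- small_vertebra()
  mir <- m
  mir$vertices[, 1] <- -mir$vertices[, 1]
  mir$faces <- mir$faces[, c(1, 3, 2)]
  d <- signed_distances(mir, m)
  expect_gt(mean(abs(d$distance)), 0.3)
})

test_that("generation and perturbation are deterministic per seed", {
  a <- generate_vertebra(vertebra_spec("C3", subdivisions = 3L))
  b <- generate_vertebra(vertebra_spec("C3", subdivisions = 3L))
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  p1 <- perturb_mesh(a, 0.2, 1, seed = 5)
  p2 <- perturb_mesh(a, 0.2, 1, seed = 5)
  expect_identical(p1$vertices, p2$vertices)
  p3 <- perturb_mesh(a, 0.2, 1, seed = 6)
  expect_false(identical(p1$vertices, p3$vertices))
  # the caller's RNG stream is left untouched
  set.seed(123)
  before <- .Random.seed
  invisible(perturb_mesh(a, 0.1, 1, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("remeshing breaks vertex correspondence but stays on-surface", {
  m <- small_vertebra()
  p <- perturb_mesh(m, 0, 1, seed = 2)
  # no output vertex coincides with an input vertex
  key_in <- paste(round(m$vertices[, 1], 9), round(m$vertices[, 2], 9),
                  round(m$vertices[, 3], 9))
  key_out <- paste(round(p$vertices[, 1], 9), round(p$vertices[, 2], 9),
                   round(p$vertices[, 3], 9))
  expect_equal(length(intersect(key_in, key_out)), 0L)
  # resampled vertices lie on the original surface
  rep <- deviation_report(signed_distances(p, m), level = "C5")
  expect_lt(rep$mean_absolute_deviation, 0.05)
})

test_that("normal-direction noise reproduces the half-normal mean", {
  m <- small_vertebra()
  p <- perturb_mesh(m, 0.2, 1, seed = 11)
  rep <- deviation_report(signed_distances(p, m), level = "C5")
  expect_equal(rep$mean_absolute_deviation, 0.2 * sqrt(2 / pi),
               tolerance = 0.15)
  # signed mean stays near zero (noise is zero-mean)
  expect_lt(abs(rep$average_distance), 0.03)
})

test_that("motion scenarios carry identity neutrals and injected angles", {
  sc <- make_scenario("ar")
  for (lev in sc$levels) {
    tn <- sc$transforms[[lev]]$neutral
    expect_equal(tn$rotation, diag(3))
    expect_equal(tn$translation, c(0, 0, 0))
  }
  inj <- sc$injected
  c12 <- inj[inj$level_pair == "C1-C2" & inj$posture == "left_rotation", ]
  expect_equal(c12$beta, 30)
  expect_lt(c12$gamma, 0)  # coupled bend opposite to the rotation
  # prescribed joint angles are exactly recoverable from the transforms
  # through the frame/kinematics chain
  frames <- lapply(sc$levels, function(lev) {
    structure(list(origin = sc$origins[[lev]], x_axis = c(1, 0, 0),
                   y_axis = c(0, 1, 0), z_axis = c(0, 0, 1), level = lev),
              class = "anatomical_frame")
  })
  names(frames) <- sc$levels
  for (pr in unique(inj$level_pair)) {
    row <- intervertebral_6dof(frames, sc$transforms, pr, "left_rotation")
    want <- inj[inj$level_pair == pr & inj$posture == "left_rotation", ]
    expect_equal(row$beta, want$beta, tolerance = 1e-9)
    expect_equal(row$alpha, want$alpha, tolerance = 1e-9)
    expect_equal(row$gamma, want$gamma, tolerance = 1e-9)
    expect_equal(abs(row$tx) + abs(row$ty) + abs(row$tz), 0,
                 tolerance = 1e-9)
  }
  expect_error(make_scenario("ar", magnitudes = c("C1-C2" = 90)),
               "60")
  sc2 <- make_scenario("fe")
  expect_true(all(c("flexion", "extension") %in% sc2$postures))
})
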