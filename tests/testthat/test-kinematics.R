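frame_at <- function(origin, rot = diag(3)) {
  structure(list(origin = origin,
                 x_axis = rot[, 1], y_axis = rot[, 2], z_axis = rot[, 3],
                 level = NA_character_),
            class = "anatomical_frame")
}

test_that("relative pose expresses the upper frame in the lower frame", {
  f <- frame_at(c(0, 0, 0))
  expect_equal(relative_pose(f, f)$rotation, diag(3))
  expect_equal(relative_pose(f, f)$translation, c(0, 0, 0))
  up <- frame_at(c(0, 1, 0))
  expect_equal(relative_pose(up, f)$translation, c(0, 1, 0))
  # lower frame rotated: translation reported along the lower's own axes
  low <- frame_at(c(0, 0, 0), rotation_z(90))
  up2 <- frame_at(c(0, 1, 0), rotation_z(90))
  expect_equal(relative_pose(up2, low)$translation, c(1, 0, 0),
               tolerance = 1e-12)
  # known 15 deg relative rotation about the lower's y axis
  up3 <- frame_at(c(0, 1, 0), rotation_y(15))
  rel <- relative_pose(up3, f)
  expect_equal(rel$rotation, rotation_y(15), tolerance = 1e-9)
})

test_that("rotation decomposition follows the clinical sign conventions", {
  expect_equal(decompose_rotation(diag(3)),
               c(alpha = 0, gamma = 0, beta = 0))
  # +20 deg right-hand about superior y = left axial rotation: beta +20
  ang <- decompose_rotation(rotation_y(20))
  expect_equal(ang[["beta"]], 20, tolerance = 1e-10)
  expect_equal(ang[["alpha"]], 0, tolerance = 1e-10)
  expect_equal(ang[["gamma"]], 0, tolerance = 1e-10)
  # right-hand rotation about +x is flexion: alpha negative
  expect_lt(decompose_rotation(rotation_x(10))[["alpha"]], 0)
  # right-hand rotation about +z (left side rising) is right bend: gamma +
  expect_gt(decompose_rotation(rotation_z(10))[["gamma"]], 0)
})

test_that("compose(decompose) reproduces rotations to 1e-9", {
  set.seed(21)
  for (i in 1:200) {
    r <- compose_rotation(runif(1, -45, 45), runif(1, -45, 45),
                          runif(1, -45, 45))
    ang <- decompose_rotation(r)
    back <- compose_rotation(ang[["alpha"]], ang[["gamma"]],
                             ang[["beta"]])
    expect_lt(max(abs(back - r)), 1e-9)
  }
  # a composed two-axis rotation decomposes consistently
  r <- rotation_y(10) %*% rotation_x(5)
  ang <- decompose_rotation(r)
  expect_equal(compose_rotation(ang[["alpha"]], ang[["gamma"]],
                                ang[["beta"]]), r, tolerance = 1e-9)
})

test_that("small-angle decompositions agree across Euler sequences", {
  # sequences differ at second order: the spread scales with the square
  # of the angle magnitude, so physiological intervertebral angles are
  # sequence-robust
  set.seed(31)
  seqs <- c("yxz", "xyz", "zyx", "zxy")
  spread_at <- function(max_deg) {
    max(sapply(1:30, function(i) {
      r <- compose_rotation(runif(1, -max_deg, max_deg),
                            runif(1, -max_deg, max_deg),
                            runif(1, -max_deg, max_deg))
      angs <- sapply(seqs, function(s) decompose_rotation(r, s))
      max(apply(angs, 1, function(x) max(x) - min(x)))
    }))
  }
  expect_lt(spread_at(1), 0.02)
  expect_lt(spread_at(2), 0.08)
  expect_lt(spread_at(5), 0.5)
})

test_that("gimbal lock is detected and named", {
  expect_error(decompose_rotation(rotation_x(90)), "gimbal")
})

test_that("6-DOF reporting: zero at neutral, recovers constructed motion", {
  frames <- list(C3 = frame_at(c(0, 19.1, 0)), C4 = frame_at(c(0, 0, 0)))
  transforms <- list(
    C3 = list(neutral = rigid_transform(),
              flexion = rigid_transform(diag(3), c(0, 0, 1))),
    C4 = list(neutral = rigid_transform(),
              flexion = rigid_transform()))
  # neutral posture in motion mode is exactly zero
  r0 <- intervertebral_6dof(frames, transforms, "C3-C4", "neutral")
  expect_equal(unlist(r0[c("tx", "ty", "tz", "alpha", "gamma", "beta")]),
               c(tx = 0, ty = 0, tz = 0, alpha = 0, gamma = 0, beta = 0))
  # pure 1 mm anterior slide of C3 on C4
  r1 <- intervertebral_6dof(frames, transforms, "C3-C4", "flexion")
  expect_equal(r1$tz, 1, tolerance = 1e-10)
  expect_equal(abs(r1$alpha) + abs(r1$gamma) + abs(r1$beta), 0,
               tolerance = 1e-10)
  # 30 deg axial rotation about the subjacent y axis through C3's origin
  rot <- rotation_y(30)
  piv <- c(0, 19.1, 0)
  transforms$C3$left_rotation <-
    rigid_transform(rot, piv - as.numeric(rot %*% piv))
  transforms$C4$left_rotation <- rigid_transform()
  r2 <- intervertebral_6dof(frames, transforms, "C3-C4", "left_rotation")
  expect_equal(r2$beta, 30, tolerance = 1e-9)
  expect_equal(abs(r2$tx) + abs(r2$ty) + abs(r2$tz), 0, tolerance = 1e-9)
  # absolute mode reports the stacked offset instead of zero
  r3 <- intervertebral_6dof(frames, transforms, "C3-C4", "neutral",
                            mode = "absolute_pose")
  expect_equal(r3$ty, 19.1)
})

test_that("upper-on-lower and lower-on-upper poses are mutually inverse", {
  set.seed(41)
  fu <- frame_at(rnorm(3), spinekin:::random_rotation(30))
  fl <- frame_at(rnorm(3), spinekin:::random_rotation(30))
  ab <- relative_pose(fu, fl)
  ba <- relative_pose(fl, fu)
  prod <- compose(ab, ba)
  expect_equal(prod$rotation, diag(3), tolerance = 1e-10)
  expect_equal(prod$translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("missing transforms are reported with level and posture", {
  frames <- list(C3 = frame_at(c(0, 19, 0)), C4 = frame_at(c(0, 0, 0)))
  transforms <- list(C3 = list(neutral = rigid_transform()),
                     C4 = list(neutral = rigid_transform()))
  expect_error(intervertebral_6dof(frames, transforms, "C3-C4", "flexion"),
               "C3.*flexion")
})
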