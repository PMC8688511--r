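canonical_landmarks <- function() {
  landmark_set(origin_candidate = c(0, 0, 0),
               superior_reference = c(0, 10, 0),
               left_reference = c(20, 0, 0),
               right_reference = c(-20, 0, 0), level = "C5")
}

test_that("canonical landmarks give the identity frame", {
  f <- build_frame(canonical_landmarks())
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(f$x_axis, c(1, 0, 0))
  expect_equal(f$y_axis, c(0, 1, 0))
  expect_equal(f$z_axis, c(0, 0, 1))
})

test_that("frame axes are orthonormal and right-handed, origin mid-sagittal", {
  set.seed(5)
  for (i in 1:10) {
    lm <- landmark_set(rnorm(3, sd = 5), c(1, 12, 2) + rnorm(3),
                       c(18, 1, -2) + rnorm(3), c(-19, -1, -1) + rnorm(3))
    f <- build_frame(lm)
    ax <- cbind(f$x_axis, f$y_axis, f$z_axis)
    expect_equal(crossprod(ax), diag(3), tolerance = 1e-10)
    expect_equal(spinekin:::cross3(f$x_axis, f$y_axis), f$z_axis,
                 tolerance = 1e-10)
    # origin lies in the mid-sagittal plane (normal x through midpoint)
    mid <- (lm$left_reference + lm$right_reference) / 2
    expect_equal(sum((f$origin - mid) * f$x_axis), 0, tolerance = 1e-9)
  }
})

test_that("build_frame is equivariant under rigid motion of landmarks", {
  set.seed(9)
  lm <- canonical_landmarks()
  f0 <- build_frame(lm)
  for (i in 1:10) {
    t <- rigid_transform(spinekin:::random_rotation(180), rnorm(3, sd = 30))
    moved <- landmark_set(transform_points(lm$origin_candidate, t),
                          transform_points(lm$superior_reference, t),
                          transform_points(lm$left_reference, t),
                          transform_points(lm$right_reference, t))
    f1 <- build_frame(moved)
    f0t <- transform_frame(f0, t)
    expect_equal(f1$origin, f0t$origin, tolerance = 1e-9)
    expect_equal(f1$x_axis, f0t$x_axis, tolerance = 1e-9)
    expect_equal(f1$y_axis, f0t$y_axis, tolerance = 1e-9)
    expect_equal(f1$z_axis, f0t$z_axis, tolerance = 1e-9)
  }
})

test_that("swapping left/right labels flips x and z, preserves y", {
  lm <- canonical_landmarks()
  sw <- landmark_set(lm$origin_candidate, lm$superior_reference,
                     lm$right_reference, lm$left_reference)
  f <- build_frame(lm)
  g <- build_frame(sw)
  expect_equal(g$x_axis, -f$x_axis)
  expect_equal(g$y_axis, f$y_axis)
  expect_equal(g$z_axis, -f$z_axis)
})

test_that("degenerate landmark configurations are rejected by name", {
  expect_error(landmark_set(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0),
                            c(1, 0, 0)), "coincide")
  # superior reference collinear with the left-right axis
  lm <- landmark_set(c(0, 0, 0), c(5, 0, 0), c(20, 0, 0), c(-20, 0, 0))
  expect_error(build_frame(lm), "collinear")
})

test_that("transform_frame preserves orthonormality and handedness", {
  f <- build_frame(canonical_landmarks())
  # pure translation leaves axes alone
  g <- transform_frame(f, rigid_transform(diag(3), c(1, 2, 3)))
  expect_equal(g$x_axis, f$x_axis)
  expect_equal(g$origin, f$origin + c(1, 2, 3))
  # 90 deg about z maps x to y
  h <- transform_frame(f, rigid_transform(rotation_z(90)))
  expect_equal(h$x_axis, c(0, 1, 0), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:5) {
    t <- rigid_transform(spinekin:::random_rotation(180), rnorm(3))
    g <- transform_frame(f, t)
    ax <- cbind(g$x_axis, g$y_axis, g$z_axis)
    expect_equal(crossprod(ax), diag(3), tolerance = 1e-10)
    expect_equal(det(ax), 1, tolerance = 1e-10)
  }
})

test_that("landmark files round-trip in CSV and JSON", {
  lm <- canonical_landmarks()
  for (ext in c(".csv", ".json")) {
    path <- tempfile(fileext = ext)
    write_landmarks(lm, path)
    back <- read_landmarks(path, level = "C5")
    for (nm in c("origin_candidate", "superior_reference",
                 "left_reference", "right_reference"))
      expect_equal(back[[nm]], lm[[nm]], tolerance = 1e-9, info = ext)
    unlink(path)
  }
  # missing point is named in the error
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(name = "left_reference", x = 1, y = 2, z = 3), path)
  expect_error(read_landmarks(path), "origin_candidate")
  unlink(path)
})

test_that("suggested landmarks on a generated vertebra give a sane frame", {
  m <- small_vertebra()
  f <- build_frame(suggest_landmarks(m))
  # roughly anatomic: x close to +x, y close to +y
  expect_gt(sum(f$x_axis * c(1, 0, 0)), 0.9)
  expect_gt(sum(f$y_axis * c(0, 1, 0)), 0.9)
})
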