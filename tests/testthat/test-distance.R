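test_that("signed distances match hand geometry on a planar patch", {
  patch <- square_patch()
  q <- triangle_mesh(rbind(c(0.5, 0.5, 0.7),   # above the patch
                           c(0.5, 0.5, -0.2),  # below the patch
                           c(2, 0.5, 0),       # beyond the +x edge
                           c(0.25, 0.25, 0)),  # exactly on the surface
                     rbind(c(1, 2, 3), c(1, 3, 4)), validate = FALSE)
  d <- signed_distances(q, patch)$distance
  expect_equal(d[1], 0.7, tolerance = 1e-12)
  expect_equal(d[2], -0.2, tolerance = 1e-12)
  # closest point is the edge point (1, 0.5, 0)
  expect_equal(abs(d[3]), 1.0, tolerance = 1e-12)
  expect_equal(d[4], 0, tolerance = 1e-12)
})

test_that("grid-accelerated distances equal the exhaustive scan exactly", {
  m <- small_vertebra()
  q <- perturb_mesh(m, 0.3, 0.5, seed = 42)
  a <- signed_distances(q, m, method = "grid")
  b <- signed_distances(q, m, method = "brute")
  expect_identical(a$distance, b$distance)
  expect_identical(a$face, b$face)
  expect_identical(a$closest, b$closest)
})

test_that("distances agree with an independent closest-point oracle", {
  set.seed(7)
  for (target in list(tetra_mesh(), sphere_mesh(5, 1L))) {
    q <- triangle_mesh(matrix(rnorm(30 * 3, sd = 4), ncol = 3),
                       rbind(c(1, 2, 3)), validate = FALSE)
    got <- signed_distances(q, target)$distance
    want <- oracle_signed_distances(q, target)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("distance magnitudes are invariant under a common rigid motion", {
  set.seed(11)
  m <- small_vertebra()
  q <- perturb_mesh(m, 0.2, 1, seed = 3)
  d0 <- signed_distances(q, m)$distance
  for (i in 1:3) {
    t <- rigid_transform(spinekin:::random_rotation(170),
                         rnorm(3, sd = 40))
    d1 <- signed_distances(apply_transform(q, t),
                           apply_transform(m, t))$distance
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("deviation report implements its statistics and invariants", {
  rep <- deviation_report(c(0.3, -0.3), characteristic_dimension = 10)
  expect_equal(rep$average_distance, 0)
  expect_equal(rep$mean_absolute_deviation, 0.3)
  expect_equal(rep$mean_deviation, 0.3)
  expect_equal(rep$max_positive, 0.3)
  expect_equal(rep$max_negative, -0.3)
  expect_equal(rep$std_positive, 0)  # singleton subsets report 0
  # uniform offset: two parallel patches h apart
  patch <- square_patch()
  lifted <- patch
  lifted$vertices[, 3] <- lifted$vertices[, 3] + 0.5
  d <- signed_distances(lifted, patch)
  r2 <- deviation_report(d, characteristic_dimension = 1)
  expect_equal(r2$average_distance, 0.5, tolerance = 1e-12)
  expect_equal(r2$mean_absolute_deviation, 0.5, tolerance = 1e-12)
  expect_equal(r2$std_positive, 0, tolerance = 1e-12)
  # self-comparison yields all-zero statistics
  m <- small_vertebra()
  rs <- deviation_report(signed_distances(m, m), level = "C5")
  expect_equal(rs$mean_absolute_deviation, 0, tolerance = 1e-12)
  expect_equal(rs$mean_deviation, 0, tolerance = 1e-12)
  # all-zero field is a valid report, not an error
  expect_equal(deviation_report(rep(0, 5), 10)$mean_deviation, 0)
  # general invariants on a random field
  set.seed(2)
  d <- rnorm(500, 0.1, 0.3)
  r3 <- deviation_report(d, characteristic_dimension = 11.9)
  expect_lte(r3$max_negative, r3$average_distance)
  expect_lte(r3$average_distance, r3$max_positive)
  expect_lte(r3$mean_absolute_deviation, r3$mean_deviation)
  expect_lte(r3$mean_deviation, max(abs(r3$max_positive),
                                    abs(r3$max_negative)))
})

test_that("concentric spheres report the analytic radial offset", {
  inner <- sphere_mesh(10, 3L)
  outer <- sphere_mesh(10.5, 3L)
  rep <- deviation_report(signed_distances(outer, inner),
                          characteristic_dimension = 10)
  # vertices of the outer sphere sit ~0.5 mm outside the inner surface,
  # minus the small chordal sag of the discretized inner sphere
  expect_equal(rep$average_distance, 0.5, tolerance = 0.02)
  expect_gt(rep$average_distance, 0.45)
})

test_that("angular deviation estimate is the small-angle linear map", {
  expect_equal(estimate_angular_deviation(0.06, 11.9),
               0.06 / 11.9 * 180 / pi, tolerance = 1e-12)
  expect_equal(estimate_angular_deviation(0, 5), 0)
  # linear in deviation, inverse-linear in dimension
  expect_equal(estimate_angular_deviation(0.2, 10),
               2 * estimate_angular_deviation(0.1, 10))
  expect_equal(estimate_angular_deviation(0.1, 20),
               estimate_angular_deviation(0.1, 10) / 2)
  expect_error(estimate_angular_deviation(0.1, 0), "positive")
  expect_error(estimate_angular_deviation(0.1, -3), "positive")
})

test_that("deviation CSV has the documented column order", {
  m <- small_vertebra()
  q <- perturb_mesh(m, 0.1, 1, seed = 5)
  rep <- deviation_report(signed_distances(q, m), level = "C5")
  path <- tempfile(fileext = ".csv")
  write_deviation_csv(rep, path)
  tab <- read.csv(path)
  expect_identical(names(tab),
                   c("level", "average_distance", "max_positive",
                     "max_negative", "std_positive", "std_negative",
                     "angular_prediction_pos", "angular_prediction_neg",
                     "mean_deviation", "mean_absolute_deviation"))
  unlink(path)
})
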