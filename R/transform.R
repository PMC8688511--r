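#' Rigid (SE(3)) transform
#'
#' A proper rigid-body transform: `x -> R x + t` with `R` a 3 x 3 rotation
#' (orthonormal, det +1) and `t` a translation in mm. Construction checks
#' orthonormality and handedness to 1e-8 and re-orthonormalizes via SVD,
#' so numerical drift never accumulates through composition.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector (mm).
#' @return object of class `rigid_transform` with elements `rotation`,
#'   `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (any(!is.finite(rotation)) || any(!is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-8)
    stop("rigid_transform: rotation is not orthonormal (deviation ",
         format(err), ")")
  if (det(rotation) < 0)
    stop("rigid_transform: rotation has det -1 (reflection, not rotation)")
  structure(list(rotation = orthonormalize(rotation),
                 translation = translation),
            class = "rigid_transform")
}

# project a near-rotation onto SO(3) (closest in Frobenius norm)
orthonormalize <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    s$v[, 3] <- -s$v[, 3]
    r <- s$u %*% t(s$v)
  }
  r
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# total rotation angle of a rotation matrix, degrees
rotation_angle <- function(r) {
  c_ang <- (sum(diag(r)) - 1) / 2
  acos(max(-1, min(1, c_ang))) * 180 / pi
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` maps `x` to `a(b(x))`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return the composed [rigid_transform()].
#' @export
compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert <- function(t) {
  rt <- t(t$rotation)
  rigid_transform(rt, -as.numeric(rt %*% t$translation))
}

#' Apply a rigid transform to a mesh
#'
#' Every vertex `v` maps to `R v + t`; faces and metadata are unchanged.
#'
#' @param mesh a [triangle_mesh()].
#' @param t a [rigid_transform()].
#' @return the transformed [triangle_mesh()].
#' @export
apply_transform <- function(mesh, t) {
  mesh$vertices <- transform_points(mesh$vertices, t)
  mesh
}

#' Apply a rigid transform to a point matrix
#'
#' @param points n x 3 matrix or length-3 vector.
#' @param t a [rigid_transform()].
#' @return transformed points, same shape as the input.
#' @export
transform_points <- function(points, t) {
  if (is.null(dim(points))) {
    as.numeric(t$rotation %*% points) + t$translation
  } else {
    sweep(points %*% t(t$rotation), 2, t$translation, "+")
  }
}

#' Elementary rotations
#'
#' Right-hand-rule rotation matrices about the coordinate axes.
#'
#' @param degrees rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_x <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rotation_x
#' @export
rotation_y <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rotation_x
#' @export
rotation_z <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# uniform random rotation with total angle <= max_degrees (random axis)
random_rotation <- function(max_degrees) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -max_degrees, max_degrees) * pi / 180
  axis_angle_matrix(ax, ang)
}

axis_angle_matrix <- function(axis, angle_rad) {
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle_rad) * k + (1 - cos(angle_rad)) * (k %*% k)
}

#' Serialize / read a rigid transform as JSON
#'
#' The rotation is stored as nine entries in row-major order together with
#' the translation and a convention note (`x' = R x + t`, mm).
#'
#' @param t a [rigid_transform()].
#' @param path JSON file path.
#' @return `write_transform_json`: `path`, invisibly;
#'   `read_transform_json`: a [rigid_transform()].
#' @export
write_transform_json <- function(t, path) {
  obj <- transform_to_list(t)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_from_list(obj)
}

transform_to_list <- function(t) {
  list(rotation_row_major = as.numeric(t(t$rotation)),
       translation_mm = t$translation,
       convention = "x_target = R %*% x_moving + t; units mm")
}

transform_from_list <- function(obj) {
  rigid_transform(matrix(as.numeric(obj$rotation_row_major), 3, 3,
                         byrow = TRUE),
                  as.numeric(obj$translation_mm))
}
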