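#' Pose of one anatomic frame relative to another
#'
#' Expresses the upper vertebra's frame in the subjacent (lower)
#' vertebra's frame: rotation `R_l' R_u` and translation
#' `R_l' (o_u - o_l)`, where the `R` are the frame axis matrices and `o`
#' the origins. The translation components are therefore the origin
#' displacement measured along the lower vertebra's anatomic axes
#' (x left, y superior, z anterior).
#'
#' @param upper,lower `anatomical_frame` objects.
#' @return a [rigid_transform()] (upper pose in lower coordinates).
#' @export
relative_pose <- function(upper, lower) {
  rl <- frame_rotation(lower)
  ru <- frame_rotation(upper)
  rigid_transform(crossprod(rl, ru),
                  as.numeric(crossprod(rl, upper$origin - lower$origin)))
}

#' Decompose an intervertebral rotation into clinical angles
#'
#' Splits a relative rotation matrix into flexion-extension (alpha),
#' lateral bending (gamma), and axial rotation (beta) using an intrinsic
#' Tait-Bryan sequence, by default y-x-z (axial rotation, then
#' flexion-extension, then lateral bending). Sign conventions follow the
#' clinical reporting convention: alpha is flexion (-) / extension (+),
#' so `alpha = -theta_x` (a right-hand rotation about the leftward +x
#' axis tips the vertebra into flexion); gamma is lateral bending
#' left (-) / right (+), so `gamma = +theta_z`; beta is axial rotation
#' right (-) / left (+), so `beta = +theta_y` (a right-hand rotation
#' about the superior +y axis turns the anterior aspect leftward).
#'
#' For the small intervertebral angles of physiological cervical motion
#' the choice of sequence is immaterial to within a few hundredths of a
#' degree; the sequence is still configurable for sensitivity checks.
#'
#' @param r 3 x 3 rotation matrix (orthonormal, det +1).
#' @param sequence intrinsic axis order, a permutation of `"x"`, `"y"`,
#'   `"z"` as a 3-character string; default `"yxz"`.
#' @return named numeric vector `c(alpha, gamma, beta)` in degrees.
#' @export
decompose_rotation <- function(r, sequence = "yxz") {
  ax <- decompose_euler(r, sequence)
  c(alpha = -ax[["x"]], gamma = ax[["z"]], beta = ax[["y"]])
}

# intrinsic Tait-Bryan decomposition R = R_i(a) R_j(b) R_k(c);
# returns angles named by axis, degrees
decompose_euler <- function(r, sequence = "yxz") {
  axes <- strsplit(sequence, "")[[1]]
  if (length(axes) != 3L || anyDuplicated(axes) ||
      !all(axes %in% c("x", "y", "z")))
    stop("sequence must be a permutation of x, y, z")
  idx <- match(axes, c("x", "y", "z"))
  i <- idx[1]; j <- idx[2]; k <- idx[3]
  sigma <- levi_civita(i, j, k)
  s <- max(-1, min(1, sigma * r[i, k]))
  if (abs(abs(s) - 1) < 1e-6)
    stop("decompose_rotation: gimbal lock (middle angle at +/-90 deg) ",
         "for sequence ", sequence)
  b <- asin(s)
  a <- atan2(-sigma * r[j, k], r[k, k])
  cc <- atan2(-sigma * r[i, j], r[i, i])
  out <- c(a, b, cc) * 180 / pi
  names(out) <- axes
  out[c("x", "y", "z")]
}

levi_civita <- function(i, j, k) {
  if (identical(c(i, j, k), c(1L, 2L, 3L)) ||
      identical(c(i, j, k), c(2L, 3L, 1L)) ||
      identical(c(i, j, k), c(3L, 1L, 2L))) 1 else -1
}

#' Rebuild a rotation matrix from clinical angles
#'
#' Inverse of [decompose_rotation()]: composes the intrinsic sequence
#' from `(alpha, gamma, beta)` under the same sign conventions.
#'
#' @param alpha flexion (-) / extension (+) angle, degrees.
#' @param gamma lateral bending left (-) / right (+) angle, degrees.
#' @param beta axial rotation right (-) / left (+) angle, degrees.
#' @param sequence intrinsic axis order (default `"yxz"`).
#' @return 3 x 3 rotation matrix.
#' @export
compose_rotation <- function(alpha, gamma, beta, sequence = "yxz") {
  per_axis <- c(x = -alpha, z = gamma, y = beta)
  axes <- strsplit(sequence, "")[[1]]
  rot <- diag(3)
  for (ax in axes) {
    rfun <- switch(ax, x = rotation_x, y = rotation_y, z = rotation_z)
    rot <- rot %*% rfun(per_axis[[ax]])
  }
  rot
}

#' Six-degree-of-freedom intervertebral kinematics at one posture
#'
#' Carries the neutral-pose anatomic frames of an adjacent vertebra pair
#' to a posture via the per-level registration transforms, computes the
#' pose of the upper frame relative to the lower (subjacent) frame, and
#' reports translations (mm, in the lower frame's axes: x right(-)/
#' left(+), y inferior(-)/superior(+), z posterior(-)/anterior(+)) and
#' rotations (degrees: alpha flexion(-)/extension(+), gamma lateral
#' bending left(-)/right(+), beta axial rotation right(-)/left(+)).
#'
#' In `"motion_from_neutral"` mode (the default) the reported pose is the
#' joint displacement from the neutral configuration,
#' `relative_pose_neutral^-1 o relative_pose_posture`, so the neutral
#' posture reports exactly zero motion. `"absolute_pose"` reports the
#' posture's relative pose directly.
#'
#' @param neutral_frames named list of `anatomical_frame` objects per
#'   level (built on the neutral models).
#' @param level_transforms nested named list
#'   `level_transforms[[level]][[posture]]` of [rigid_transform()]
#'   objects carrying each neutral model to each posture.
#' @param level_pair character like `"C1-C2"` (upper-lower).
#' @param posture posture label.
#' @param mode `"motion_from_neutral"` or `"absolute_pose"`.
#' @param sequence Euler sequence passed to [decompose_rotation()].
#' @return one-row data.frame of class `six_dof_result` with columns
#'   `level_pair`, `posture`, `mode`, `tx`, `ty`, `tz` (mm), `alpha`,
#'   `gamma`, `beta` (degrees).
#' @export
intervertebral_6dof <- function(neutral_frames, level_transforms,
                                level_pair, posture,
                                mode = c("motion_from_neutral",
                                         "absolute_pose"),
                                sequence = "yxz") {
  mode <- match.arg(mode)
  lv <- strsplit(level_pair, "-", fixed = TRUE)[[1]]
  if (length(lv) != 2L)
    stop("level_pair must look like 'C1-C2': ", level_pair)
  upper_lv <- lv[1]; lower_lv <- lv[2]
  for (l in c(upper_lv, lower_lv)) {
    if (is.null(neutral_frames[[l]]))
      stop("missing neutral frame for level ", l)
    if (is.null(level_transforms[[l]]) ||
        is.null(level_transforms[[l]][[posture]]))
      stop("missing transform for level ", l, " at posture ", posture)
  }
  fu <- transform_frame(neutral_frames[[upper_lv]],
                        level_transforms[[upper_lv]][[posture]])
  fl <- transform_frame(neutral_frames[[lower_lv]],
                        level_transforms[[lower_lv]][[posture]])
  pose <- relative_pose(fu, fl)
  if (mode == "motion_from_neutral") {
    pose_n <- relative_pose(neutral_frames[[upper_lv]],
                            neutral_frames[[lower_lv]])
    pose <- compose(invert(pose_n), pose)
  }
  ang <- decompose_rotation(pose$rotation, sequence)
  out <- data.frame(level_pair = level_pair, posture = posture, mode = mode,
                    tx = pose$translation[1], ty = pose$translation[2],
                    tz = pose$translation[3],
                    alpha = ang[["alpha"]], gamma = ang[["gamma"]],
                    beta = ang[["beta"]],
                    stringsAsFactors = FALSE)
  class(out) <- c("six_dof_result", "data.frame")
  out
}

#' Write a kinematics table as CSV
#'
#' One row per (level pair, posture) with translations (mm) and rotations
#' (degrees).
#'
#' @param rows a `six_dof_result` or list of them.
#' @param path output CSV path.
#' @return the combined data.frame, invisibly.
#' @export
write_kinematics_csv <- function(rows, path) {
  if (inherits(rows, "six_dof_result")) rows <- list(rows)
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
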