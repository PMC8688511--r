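#' Anatomic landmark set for one vertebra
#'
#' The four named points that define a vertebra's anatomic coordinate
#' system: the frame origin candidate (most posterior-inferior point of
#' the vertebral body in the mid-sagittal plane), a point defining the
#' superior direction from the origin, and a bilaterally symmetric
#' left/right pair (e.g. transverse-process tips) defining the left axis
#' and the mid-sagittal plane. Coordinates are in the mesh's mm system.
#'
#' @param origin_candidate,superior_reference,left_reference,right_reference
#'   length-3 numeric points (mm).
#' @param level optional vertebra level label.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(origin_candidate, superior_reference,
                         left_reference, right_reference,
                         level = NA_character_) {
  pts <- list(origin_candidate = as.numeric(origin_candidate),
              superior_reference = as.numeric(superior_reference),
              left_reference = as.numeric(left_reference),
              right_reference = as.numeric(right_reference))
  for (nm in names(pts))
    if (length(pts[[nm]]) != 3L || any(!is.finite(pts[[nm]])))
      stop("landmark_set: ", nm, " must be a finite 3D point")
  if (sqrt(sum((pts$left_reference - pts$right_reference)^2)) < 1e-9)
    stop("landmark_set: left_reference and right_reference coincide")
  structure(c(pts, list(level = level)), class = "landmark_set")
}

#' Build the anatomic coordinate frame from landmarks
#'
#' Constructs the per-vertebra frame: origin at the most
#' posterior-inferior point of the vertebral body projected onto the
#' mid-sagittal plane, x axis positive leftward, y axis positive
#' superior, z axis positive anterior (right-handed). The left-right axis
#' is primary: `x = unit(left - right)`; `y` is the unit superior
#' direction with its x component removed (Gram-Schmidt); `z = x cross y`.
#' The mid-sagittal plane passes through the midpoint of the left/right
#' references with normal x.
#'
#' @param landmarks a [landmark_set()].
#' @return object of class `anatomical_frame`: list with `origin` (mm)
#'   and unit axes `x_axis` (left), `y_axis` (superior), `z_axis`
#'   (anterior), plus the level label.
#' @export
build_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  x <- landmarks$left_reference - landmarks$right_reference
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9)
    stop("build_frame: left/right references coincide (degenerate pair)")
  x <- x / nx
  up <- landmarks$superior_reference - landmarks$origin_candidate
  up_perp <- up - sum(up * x) * x
  nup <- sqrt(sum(up_perp^2))
  if (nup < 1e-9 * max(1, sqrt(sum(up^2))))
    stop("build_frame: superior_reference is collinear with the ",
         "left-right axis (degenerate pair: superior vs left/right)")
  y <- up_perp / nup
  z <- cross3(x, y)
  mid <- (landmarks$left_reference + landmarks$right_reference) / 2
  o <- landmarks$origin_candidate
  origin <- o - sum((o - mid) * x) * x  # project into mid-sagittal plane
  structure(list(origin = origin, x_axis = x, y_axis = y, z_axis = z,
                 level = landmarks$level),
            class = "anatomical_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("anatomical_frame%s: origin (%.2f, %.2f, %.2f) mm\n",
              if (!is.na(x$level)) paste0(" ", x$level) else "",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# frame axes as columns of a rotation matrix (frame -> world)
frame_rotation <- function(frame) {
  cbind(frame$x_axis, frame$y_axis, frame$z_axis, deparse.level = 0)
}

#' Carry an anatomic frame through a rigid transform
#'
#' Maps a neutral-pose frame to an end position via a registration
#' transform: the origin moves with the full transform, the axes rotate.
#'
#' @param frame an [build_frame()] result.
#' @param t a [rigid_transform()].
#' @return the transformed `anatomical_frame`.
#' @export
transform_frame <- function(frame, t) {
  structure(list(origin = transform_points(frame$origin, t),
                 x_axis = as.numeric(t$rotation %*% frame$x_axis),
                 y_axis = as.numeric(t$rotation %*% frame$y_axis),
                 z_axis = as.numeric(t$rotation %*% frame$z_axis),
                 level = frame$level),
            class = "anatomical_frame")
}

#' Read / write landmark files
#'
#' Landmarks are stored either as a CSV with columns
#' `name, x, y, z` (names `origin_candidate`, `superior_reference`,
#' `left_reference`, `right_reference`) or as a JSON object mapping each
#' name to a 3-vector. Coordinates are mm in the mesh coordinate system.
#'
#' @param path file path (`.csv` or `.json`).
#' @param level optional level label attached to the set.
#' @return `read_landmarks`: a [landmark_set()].
#' @export
read_landmarks <- function(path, level = NA_character_) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  need <- c("origin_candidate", "superior_reference", "left_reference",
            "right_reference")
  if (ext == "csv") {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "x", "y", "z") %in% names(tab)))
      stop("landmark CSV must have columns name, x, y, z: ", path)
    rownames(tab) <- tab$name
    miss <- setdiff(need, tab$name)
    if (length(miss))
      stop("landmark file missing points: ", paste(miss, collapse = ", "))
    pts <- lapply(need, function(nm) as.numeric(tab[nm, c("x", "y", "z")]))
  } else if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    miss <- setdiff(need, names(obj))
    if (length(miss))
      stop("landmark file missing points: ", paste(miss, collapse = ", "))
    pts <- lapply(need, function(nm) as.numeric(obj[[nm]]))
  } else stop("unsupported landmark file format: ", path)
  landmark_set(pts[[1]], pts[[2]], pts[[3]], pts[[4]], level = level)
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()] to write.
#' @export
write_landmarks <- function(landmarks, path) {
  ext <- tolower(tools::file_ext(path))
  need <- c("origin_candidate", "superior_reference", "left_reference",
            "right_reference")
  if (ext == "csv") {
    tab <- do.call(rbind, lapply(need, function(nm) {
      p <- landmarks[[nm]]
      data.frame(name = nm, x = p[1], y = p[2], z = p[3])
    }))
    write.csv(tab, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(landmarks[need], path, digits = NA)
  } else stop("unsupported landmark file format: ", path)
  invisible(path)
}

#' Export an anatomic frame as JSON
#'
#' @param frame an `anatomical_frame`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(list(origin = frame$origin, x_axis = frame$x_axis,
                            y_axis = frame$y_axis, z_axis = frame$z_axis,
                            level = frame$level),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Suggest landmarks on a synthetic or roughly axis-aligned vertebra mesh
#'
#' Extreme-point heuristic intended for generated fixtures and sanity
#' checks only: takes the lateral extremes as left/right references, the
#' lowest posterior mid-sagittal vertex as origin candidate, and the
#' highest mid-sagittal vertex as superior reference. Manually placed or
#' file-specified landmarks are authoritative for real anatomy.
#'
#' @param mesh a [triangle_mesh()] in roughly anatomic orientation
#'   (x left, y superior, z anterior).
#' @return a [landmark_set()].
#' @export
suggest_landmarks <- function(mesh) {
  v <- mesh$vertices
  ctr <- mesh_centroid(mesh)
  left <- v[which.max(v[, 1]), ]
  right <- v[which.min(v[, 1]), ]
  sag <- v[abs(v[, 1] - ctr[1]) < diff(range(v[, 1])) * 0.15, , drop = FALSE]
  if (nrow(sag) < 2L) sag <- v
  # posterior-inferior: low y, low z (posterior is -z), body region only
  # (exclude the far-posterior spinous process by staying near mid-z)
  body <- sag[sag[, 3] > ctr[3] - 0.3 * diff(range(v[, 3])), , drop = FALSE]
  post_inf <- body[which.min(body[, 2] + 0.5 * (body[, 3] - ctr[3])), ]
  # superior reference defines a direction with the origin, not a surface
  # point: place it directly superior to the origin candidate at the
  # mesh's vertical extent
  sup <- post_inf + c(0, diff(range(v[, 2])), 0)
  landmark_set(post_inf, sup, left, right, level = mesh$label)
}
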