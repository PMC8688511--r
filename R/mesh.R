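#' Triangle surface mesh of a single vertebra
#'
#' Constructs a validated triangle mesh. Vertices are in millimetres.
#' Validation enforces that every face references an existing vertex, that
#' no face is degenerate (zero area), and that the mesh forms a single
#' connected component — the defects that break closest-point queries and
#' rigid registration downstream.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param label vertebra level identifier, e.g. `"C5"` (optional).
#' @param posture posture label, one of `"neutral"`, `"flexion"`,
#'   `"extension"`, `"left_bend"`, `"right_bend"`, `"left_rotation"`,
#'   `"right_rotation"` (optional).
#' @param validate logical; skip validation only when the input is known
#'   valid (e.g. internally generated).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `label`, `posture`.
#' @export
triangle_mesh <- function(vertices, faces, label = NA_character_,
                          posture = NA_character_, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!is.na(posture) && !posture %in% POSTURES)
    stop("unknown posture label: ", posture)
  mesh <- structure(list(vertices = vertices, faces = faces,
                         label = label, posture = posture),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (!is.na(x$label)) cat(sprintf(" [%s]", x$label))
  if (!is.na(x$posture)) cat(sprintf(" (%s)", x$posture))
  bb <- mesh_bbox(x)
  cat(sprintf("\n  bbox extent (mm): x %.2f, y %.2f, z %.2f\n",
              bb[1, 2] - bb[1, 1], bb[2, 2] - bb[2, 1], bb[3, 2] - bb[3, 1]))
  invisible(x)
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0L || nrow(f) == 0L)
    stop("mesh validation: empty mesh (no vertices or no faces)")
  if (any(!is.finite(v)))
    stop("mesh validation: non-finite vertex coordinates")
  if (any(f < 1L) || any(f > nrow(v)))
    stop("mesh validation: face indices out of range")
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area2 <- sqrt(rowSums(cr^2))
  if (any(area2 < 1e-12))
    stop("mesh validation: degenerate (zero-area) faces at rows ",
         paste(utils::head(which(area2 < 1e-12), 5L), collapse = ", "))
  comp <- mesh_components(mesh)
  if (max(comp) > 1L)
    stop("mesh validation: mesh has ", max(comp),
         " connected components; expected a single component")
  invisible(mesh)
}

# connected-component labels over the vertex graph (union-find)
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  e1 <- c(f[, 1], f[, 2])
  e2 <- c(f[, 2], f[, 3])
  for (k in seq_along(e1)) {
    a <- find(e1[k]); b <- find(e2[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# each interior edge of a closed manifold mesh appears in exactly two faces
mesh_edge_counts <- function(mesh) {
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  key <- paste(pmin(i, j), pmax(i, j))
  table(key)
}

is_closed_mesh <- function(mesh) all(mesh_edge_counts(mesh) == 2L)

is_manifold_mesh <- function(mesh) all(mesh_edge_counts(mesh) <= 2L)

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return 3 x 2 matrix with rows x, y, z and columns min, max (mm).
#' @export
mesh_bbox <- function(mesh) {
  v <- mesh$vertices
  out <- cbind(min = apply(v, 2, min), max = apply(v, 2, max))
  rownames(out) <- c("x", "y", "z")
  out
}

#' Vertex centroid of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return length-3 numeric vector (mm).
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

# per-face unit outward normals (counter-clockwise winding)
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
             ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
             ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  n / sqrt(rowSums(n^2))
}

# area-weighted unit vertex normals
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])  # area-weighted
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    idx <- f[, k]
    n[, 1] <- n[, 1] + tapply_add(fn[, 1], idx, nrow(v))
    n[, 2] <- n[, 2] + tapply_add(fn[, 2], idx, nrow(v))
    n[, 3] <- n[, 3] + tapply_add(fn[, 3], idx, nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  s <- rowsum(values, index)
  out[as.integer(rownames(s))] <- s
  out
}
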