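#' Read a triangle mesh from STL or PLY
#'
#' Reads binary or ASCII STL and ASCII PLY surface models. STL stores a
#' triangle soup, so coincident vertices are merged on input to recover
#' shared connectivity. Coordinates are assumed to be millimetres. The
#' mesh is validated (non-empty, no degenerate faces, single connected
#' component, manifold edges).
#'
#' @param path file path.
#' @param format `"STL"`, `"PLY"`, or `"auto"` (from the file extension).
#' @param label,posture optional metadata attached to the mesh.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "STL", "PLY"),
                      label = NA_character_, posture = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "STL", ply = "PLY",
                     stop("cannot infer mesh format from extension: ", path))
  }
  raw <- if (format == "STL") read_stl(path) else read_ply(path)
  merged <- merge_vertices(raw$vertices, raw$faces)
  mesh <- triangle_mesh(merged$vertices, merged$faces, label = label,
                        posture = posture, validate = FALSE)
  validate_mesh(mesh)
  if (!is_manifold_mesh(mesh))
    stop("mesh validation: non-manifold edges (an edge is shared by more ",
         "than two faces) in ", path)
  mesh
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"STL"` (binary), `"STL_ascii"`, or `"PLY"` (ASCII);
#'   `"auto"` picks binary STL or ASCII PLY from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "STL", "STL_ascii", "PLY")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "STL", ply = "PLY",
                     stop("cannot infer mesh format from extension: ", path))
  }
  switch(format,
         STL = write_stl_binary(mesh, path),
         STL_ascii = write_stl_ascii(mesh, path),
         PLY = write_ply(mesh, path))
  invisible(path)
}

# ---- STL ----

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 5L)
  if (length(header) < 5L) stop("truncated STL file: ", path)
  is_ascii <- identical(rawToChar(header), "solid")
  if (is_ascii) {
    # an ASCII file must also contain "facet"; some binary files start
    # with the bytes of "solid" in the 80-byte header
    txt <- readLines(path, warn = FALSE)
    if (any(grepl("facet", txt, fixed = TRUE)))
      return(parse_stl_ascii(txt, path))
  }
  close(con)
  on.exit()
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(ntri) == 0L || is.na(ntri) || ntri <= 0L)
    stop("truncated or empty STL file: ", path)
  expect <- ntri * 50L
  blob <- readBin(con, "raw", n = expect)
  if (length(blob) < expect) stop("truncated STL file: ", path)
  # each record: 12 floats (normal + 3 vertices) + 2-byte attribute
  idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L +
    rep(seq_len(48L), times = ntri)
  vals <- readBin(blob[idx], "numeric", n = ntri * 12L, size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 12L, byrow = TRUE)
  verts <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

parse_stl_ascii <- function(txt, path) {
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("truncated or malformed ASCII STL file: ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  if (any(!is.finite(verts))) stop("malformed ASCII STL file: ", path)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "spinekin binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  tri <- cbind(n, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
  vals <- as.numeric(t(tri))
  for (i in seq_len(nrow(f))) {
    writeBin(vals[(i - 1L) * 12L + 1:12], con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid spinekin", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      p <- v[f[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]),
                 con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid spinekin", con)
}

# ---- PLY (ASCII) ----

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3L || trimws(txt[1]) != "ply")
    stop("not a PLY file: ", path)
  endh <- match("end_header", trimws(txt))
  if (is.na(endh)) stop("malformed PLY header (no end_header): ", path)
  head <- trimws(txt[seq_len(endh)])
  fmt <- grep("^format ", head, value = TRUE)
  if (!any(grepl("ascii", fmt)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex ", head, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face ", head, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  body <- trimws(txt[(endh + 1L):length(txt)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) stop("truncated PLY file: ", path)
  vrows <- strsplit(body[seq_len(nv)], "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(x) as.numeric(x[1:3])))
  frows <- strsplit(body[nv + seq_len(nf)], "\\s+")
  faces <- do.call(rbind, lapply(frows, function(x) {
    cnt <- as.integer(x[1])
    if (is.na(cnt) || cnt != 3L)
      stop("PLY face with ", x[1], " vertices; only triangles supported")
    as.integer(x[2:4]) + 1L
  }))
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment spinekin surface model",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
}

# merge exactly coincident vertices (triangle-soup formats such as STL)
merge_vertices <- function(vertices, faces) {
  key <- paste(vertices[, 1], vertices[, 2], vertices[, 3])
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  newv <- vertices[uk, , drop = FALSE]
  newf <- matrix(map[faces], ncol = 3L)
  list(vertices = newv, faces = newf)
}
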