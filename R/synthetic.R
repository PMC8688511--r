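#' Specification of a synthetic vertebra mesh
#'
#' Parameters for the synthetic vertebra generator. Default dimensions
#' per level are the built-in typical cervical dimensions
#' ([vertebra_dimensions()]). The generated fixtures are stylized test
#' bodies, not anatomical atlases: what they reproduce from real
#' segmented vertebrae is the overall size, a complex asymmetric surface
#' (so registration has a unique optimum), and the absence of vertex
#' correspondence between independently meshed copies.
#'
#' @param level vertebra level `"C1"`..`"C7"`.
#' @param height,width,length overall bounding-box dimensions (mm);
#'   defaults are the per-level built-in constants.
#' @param noise_sigma surface noise standard deviation (mm) used when the
#'   spec is passed to [perturb_mesh()].
#' @param remesh_factor target face-count ratio for remeshing.
#' @param subdivisions icosphere subdivision level controlling mesh
#'   resolution (level 4, the default, gives 2562 vertices / 5120 faces;
#'   level 3 gives 642 / 1280).
#' @param seed random seed for perturbation.
#' @return object of class `vertebra_spec`.
#' @export
vertebra_spec <- function(level = "C5", height = NULL, width = NULL,
                          length = NULL, noise_sigma = 0.2,
                          remesh_factor = 4, subdivisions = 4L,
                          seed = 1L) {
  dims <- vertebra_dimensions()
  i <- match(level, dims$level)
  if (is.na(i)) stop("unknown vertebra level: ", level)
  height <- if (is.null(height)) dims$height[i] else height
  width <- if (is.null(width)) dims$width[i] else width
  length <- if (is.null(length)) dims$length[i] else length
  if (any(c(height, width, length) <= 0))
    stop("vertebra dimensions must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (remesh_factor <= 0 || remesh_factor > 4)
    stop("remesh_factor must be in (0, 4]")
  structure(list(level = level, height = height, width = width,
                 length = length, noise_sigma = noise_sigma,
                 remesh_factor = remesh_factor,
                 subdivisions = as.integer(subdivisions),
                 seed = as.integer(seed)),
            class = "vertebra_spec")
}

#' Generate a synthetic vertebra mesh
#'
#' Builds a closed, connected, asymmetric star-shaped surface emulating a
#' segmented cervical vertebra: an anterior body bulge, a posterior
#' spinous prominence, two (unequally sized) lateral transverse-process
#' prominences, and an off-axis superior articular prominence. The
#' surface is a radially displaced icosphere, anisotropically scaled so
#' the axis-aligned bounding box matches the spec's (width, height,
#' length) exactly in (x, y, z). The unequal lateral prominences and the
#' off-axis superior prominence remove every rotational symmetry, so
#' rigid registration of two copies has a unique optimum. Generation is
#' fully deterministic for a given spec.
#'
#' @param spec a [vertebra_spec()].
#' @return a [triangle_mesh()] with `label` set to the level and
#'   `posture` `"neutral"`.
#' @export
generate_vertebra <- function(spec) {
  stopifnot(inherits(spec, "vertebra_spec"))
  ico <- icosphere(spec$subdivisions)
  u <- ico$vertices  # unit directions
  r <- 1 +
    bump(u, c(0, -0.15, -1), 0.90, 0.060) +   # spinous process (posterior)
    bump(u, c(1, 0, -0.12), 0.55, 0.050) +    # left transverse process
    bump(u, c(-1, 0, -0.12), 0.42, 0.050) +   # right transverse process
    bump(u, c(0.35, 1, 0.25), 0.30, 0.110) +  # superior articular, off-axis
    bump(u, c(0, -0.2, 1), 0.35, 0.300)       # anterior body bulge
  v <- u * r
  # anisotropic scale: bbox exactly (width, height, length) in (x, y, z)
  target <- c(spec$width, spec$height, spec$length)
  for (k in 1:3) {
    ext <- max(v[, k]) - min(v[, k])
    ctr <- (max(v[, k]) + min(v[, k])) / 2
    v[, k] <- (v[, k] - ctr) * (target[k] / ext)
  }
  triangle_mesh(v, ico$faces, label = spec$level, posture = "neutral",
                validate = FALSE)
}

# smooth radial bump centred on unit direction d (Gaussian in 1 - cos)
bump <- function(u, d, amplitude, width) {
  d <- d / sqrt(sum(d^2))
  co <- as.numeric(u %*% d)
  amplitude * exp(-(1 - co) / width)
}

# unit icosphere by repeated midpoint subdivision of an icosahedron
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    m <- nrow(f)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))
    first <- !duplicated(key)
    midx <- nv + match(key, key[first])
    ue <- edges[first, , drop = FALSE]
    midv <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    midv <- midv / sqrt(rowSums(midv^2))
    v <- rbind(v, midv)
    ab <- midx[seq_len(m)]
    bc <- midx[m + seq_len(m)]
    ca <- midx[2L * m + seq_len(m)]
    f <- rbind(cbind(f[, 1], ab, ca), cbind(f[, 2], bc, ab),
               cbind(f[, 3], ca, bc), cbind(ab, bc, ca))
  }
  list(vertices = v, faces = f)
}

#' Remesh and perturb a mesh to emulate independent segmentation
#'
#' Produces a model of the same bone "segmented independently": the
#' surface is resampled onto a fresh, randomly rotated icosphere
#' connectivity by radial ray casting from the centroid (so no output
#' vertex coincides with an input vertex and the two meshes share no
#' correspondence), then each vertex is displaced along its local normal
#' by zero-mean Gaussian noise, emulating segmentation boundary error.
#' Deterministic for a given seed. The input mesh must be star-shaped
#' about its vertex centroid (true of all generated vertebrae).
#'
#' @param mesh a [triangle_mesh()].
#' @param noise_sigma standard deviation of normal-direction noise (mm).
#' @param remesh_factor target ratio of output to input face count, in
#'   (0, 4].
#' @param seed random seed.
#' @return a [triangle_mesh()] with the same label/posture.
#' @export
perturb_mesh <- function(mesh, noise_sigma = 0, remesh_factor = 1,
                         seed = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (remesh_factor <= 0 || remesh_factor > 4)
    stop("remesh_factor must be in (0, 4]")
  target_faces <- nrow(mesh$faces) * remesh_factor
  subdiv <- max(1L, min(5L, round(log(target_faces / 20) / log(4))))
  with_seed(seed, {
    ico <- icosphere(subdiv)
    # small random rotation of the sampling directions breaks any
    # vertex coincidence with the input mesh
    rot <- random_rotation(180)
    dirs <- ico$vertices %*% t(rot)
    ctr <- mesh_centroid(mesh)
    tt <- cpp_ray_radial(dirs, ctr, mesh$vertices, mesh$faces)
    if (any(tt <= 0))
      stop("perturb_mesh: radial resampling failed; mesh is not ",
           "star-shaped about its centroid")
    v <- sweep(dirs * tt, 2, ctr, "+")
    out <- triangle_mesh(v, ico$faces, label = mesh$label,
                         posture = mesh$posture, validate = FALSE)
    if (noise_sigma > 0) {
      n <- vertex_normals(out)
      out$vertices <- out$vertices + n * rnorm(nrow(v), 0, noise_sigma)
    }
    out
  })
}

#' Ideal landmarks for a generated vertebra
#'
#' The generator knows its own geometry, so landmark coordinates are
#' emitted analytically (exact, in the mesh's mm system): origin at the
#' posterior-inferior corner region of the body in the mid-sagittal
#' plane, superior reference directly above it, left/right references at
#' the lateral extremes. Frames built from these landmarks have exactly
#' identity axes on the neutral generated mesh.
#'
#' @param spec a [vertebra_spec()].
#' @return a [landmark_set()].
#' @export
synthetic_landmarks <- function(spec) {
  stopifnot(inherits(spec, "vertebra_spec"))
  landmark_set(
    origin_candidate = c(0, -spec$height / 2, -0.2 * spec$length),
    superior_reference = c(0, spec$height / 2, -0.2 * spec$length),
    left_reference = c(spec$width / 2, 0, -0.1 * spec$length),
    right_reference = c(-spec$width / 2, 0, -0.1 * spec$length),
    level = spec$level)
}

#' Build a multi-posture ground-truth motion scenario
#'
#' Constructs per-level, per-posture ground-truth rigid transforms for a
#' seven-level cervical spine whose intervertebral joint angles are
#' prescribed, emulating the characteristic in vivo motion patterns:
#' `"fe"` distributes flexion-extension across levels; `"lb"` distributes
#' lateral bending roughly evenly with a small opposite-direction coupled
#' axial rotation at C1-C2; `"ar"` concentrates axial rotation at C1-C2
#' (default 30 degrees, matching the dominant atlantoaxial share of head
#' rotation) with small same-direction axial rotation subaxially and a
#' small coupled lateral bend opposite to the rotation at C1-C2;
#' `"custom"` uses the supplied per-joint angles verbatim.
#'
#' C7 is the fixed base. Levels are stacked superiorly at their typical
#' heights with a 5 mm disc space; each joint rotation acts about the
#' moving (upper) vertebra's anatomic frame origin, so the prescribed
#' joint angles appear with exactly zero intervertebral translation and
#' the world transform of a level is the chain of its lower joints'
#' motions. The neutral posture is the identity for every level.
#'
#' @param name `"fe"`, `"lb"`, `"ar"`, or `"custom"`.
#' @param magnitudes named per-joint primary angle magnitudes in degrees
#'   (names `"C1-C2"` .. `"C6-C7"`); presets have defaults, `"custom"`
#'   expects a full specification as a list of per-joint
#'   `c(alpha, gamma, beta)` vectors per posture.
#' @param postures postures to include besides neutral; defaults to the
#'   pair matching the preset (e.g. left/right rotation for `"ar"`).
#' @return object of class `motion_scenario`: list with `levels`,
#'   `origins` (per-level frame origins in world/neutral coordinates),
#'   `transforms[[level]][[posture]]` ([rigid_transform()]s,
#'   neutral -> posture), and `injected` (data.frame of prescribed joint
#'   angles per level pair and posture).
#' @export
make_scenario <- function(name = c("ar", "fe", "lb", "custom"),
                          magnitudes = NULL, postures = NULL) {
  name <- match.arg(name)
  pairs <- paste0("C", 1:6, "-", "C", 2:7)
  if (name == "custom" && is.null(magnitudes))
    stop("custom scenario requires magnitudes")
  defaults <- switch(name,
    ar = c("C1-C2" = 30, "C2-C3" = 3, "C3-C4" = 3, "C4-C5" = 3,
           "C5-C6" = 2, "C6-C7" = 2),
    fe = c("C1-C2" = 6, "C2-C3" = 8, "C3-C4" = 12, "C4-C5" = 12,
           "C5-C6" = 10, "C6-C7" = 6),
    lb = c("C1-C2" = 4, "C2-C3" = 6, "C3-C4" = 6, "C4-C5" = 6,
           "C5-C6" = 6, "C6-C7" = 5),
    custom = NULL)
  if (name != "custom") {
    mags <- defaults
    if (!is.null(magnitudes)) mags[names(magnitudes)] <- magnitudes
    if (any(abs(mags) > 60))
      stop("joint angle magnitudes must be within +/-60 degrees")
    post <- if (is.null(postures)) switch(name,
      ar = c("left_rotation", "right_rotation"),
      fe = c("flexion", "extension"),
      lb = c("left_bend", "right_bend")) else postures
    joint <- list()
    for (p in post) {
      ang <- lapply(pairs, function(pr) {
        m <- mags[[pr]]
        # (alpha, gamma, beta) per clinical sign conventions
        switch(p,
          flexion = c(-m, 0, 0),
          extension = c(m, 0, 0),
          left_bend = c(0, -m, if (pr == "C1-C2") 0.25 * m else 0),
          right_bend = c(0, m, if (pr == "C1-C2") -0.25 * m else 0),
          left_rotation = c(0, if (pr == "C1-C2") -0.2 * m else 0.1 * m, m),
          right_rotation = c(0, if (pr == "C1-C2") 0.2 * m else -0.1 * m, -m),
          stop("no preset joint pattern for posture ", p))
      })
      names(ang) <- pairs
      joint[[p]] <- ang
    }
  } else {
    joint <- magnitudes
    post <- names(joint)
    for (p in post) {
      if (!all(pairs %in% names(joint[[p]])))
        stop("custom magnitudes must name every joint C1-C2 .. C6-C7")
      if (any(vapply(joint[[p]], function(a) any(abs(a) > 60), logical(1))))
        stop("joint angle magnitudes must be within +/-60 degrees")
    }
  }
  dims <- vertebra_dimensions()
  disc <- 5
  # stack meshes superiorly: C7 at 0, each level above its subjacent one
  y <- rev(cumsum(rev(c(dims$height[-7] + disc, 0))))
  mesh_offsets <- lapply(seq_len(7), function(i) c(0, y[i], 0))
  names(mesh_offsets) <- LEVELS
  # anatomic frame origin per level, in world (neutral) coordinates:
  # stacking offset plus the analytic landmark origin of the generator
  origins <- lapply(seq_len(7), function(i) {
    mesh_offsets[[i]] +
      c(0, -dims$height[i] / 2, -0.2 * dims$length[i])
  })
  names(origins) <- LEVELS
  transforms <- list()
  injected <- list()
  for (lev in LEVELS) transforms[[lev]] <-
    list(neutral = rigid_transform())
  for (p in post) {
    tr <- list("C7" = rigid_transform())
    for (i in 6:1) {
      lev <- LEVELS[i]
      lower <- LEVELS[i + 1]
      pr <- paste0(lev, "-", lower)
      a <- joint[[p]][[pr]]
      r <- compose_rotation(a[1], a[2], a[3])
      o <- origins[[lev]]  # pivot on the moving vertebra's frame origin
      m <- rigid_transform(r, o - as.numeric(r %*% o))
      tr[[lev]] <- compose(tr[[lower]], m)
      injected[[length(injected) + 1L]] <-
        data.frame(level_pair = pr, posture = p, alpha = a[1],
                   gamma = a[2], beta = a[3], tx = 0, ty = 0, tz = 0,
                   stringsAsFactors = FALSE)
    }
    for (lev in LEVELS) transforms[[lev]][[p]] <- tr[[lev]]
  }
  structure(list(name = name, levels = LEVELS, origins = origins,
                 mesh_offsets = mesh_offsets,
                 postures = c("neutral", post),
                 transforms = transforms,
                 injected = do.call(rbind, injected)),
            class = "motion_scenario")
}
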