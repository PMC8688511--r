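# Shared fixtures, built in code.

# small closed tetrahedron
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

# unit square patch in the z = 0 plane, outward normal +z
square_patch <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  triangle_mesh(v, f)
}

# icosphere mesh of given radius
sphere_mesh <- function(radius = 10, subdivisions = 3L) {
  ico <- spinekin:::icosphere(subdivisions)
  triangle_mesh(ico$vertices * radius, ico$faces)
}

# small fast vertebra for unit tests (coarser than the study default)
small_vertebra <- function(level = "C5") {
  generate_vertebra(vertebra_spec(level, subdivisions = 3L))
}

# independent pure-R closest-point oracle: minimizes |p - (a + s*ab + t*ac)|
# over the barycentric simplex by constrained quadratic minimization
# (project the unconstrained solution, then check the three edges).
oracle_closest_point <- function(p, a, b, c) {
  ab <- b - a
  ac <- c - a
  candidates <- list()
  # unconstrained stationary point of the quadratic
  g <- rbind(c(sum(ab * ab), sum(ab * ac)), c(sum(ab * ac), sum(ac * ac)))
  rhs <- c(sum(ab * (p - a)), sum(ac * (p - a)))
  st <- tryCatch(solve(g, rhs), error = function(e) c(-1, -1))
  if (st[1] >= 0 && st[2] >= 0 && sum(st) <= 1)
    candidates[[length(candidates) + 1]] <- a + st[1] * ab + st[2] * ac
  # three edges, each a 1-D clamped projection
  edge <- function(q0, q1) {
    d <- q1 - q0
    t <- sum((p - q0) * d) / sum(d * d)
    t <- max(0, min(1, t))
    q0 + t * d
  }
  candidates <- c(candidates, list(edge(a, b), edge(b, c), edge(c, a)))
  d2 <- vapply(candidates, function(q) sum((p - q)^2), numeric(1))
  candidates[[which.min(d2)]]
}

oracle_signed_distances <- function(moving, target) {
  v <- target$vertices
  f <- target$faces
  fn <- spinekin:::face_normals(target)
  vapply(seq_len(nrow(moving$vertices)), function(i) {
    p <- moving$vertices[i, ]
    best <- Inf
    best_face <- NA_integer_
    best_q <- NULL
    for (j in seq_len(nrow(f))) {
      q <- oracle_closest_point(p, v[f[j, 1], ], v[f[j, 2], ], v[f[j, 3], ])
      d2 <- sum((p - q)^2)
      if (d2 < best) {
        best <- d2
        best_face <- j
        best_q <- q
      }
    }
    s <- if (sum(fn[best_face, ] * (p - best_q)) >= 0) 1 else -1
    s * sqrt(best)
  }, numeric(1))
}

rot_err_deg <- function(r1, r2) spinekin:::rotation_angle(t(r1) %*% r2)

trans_err_mm <- function(t1, t2) sqrt(sum((t1 - t2)^2))
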