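#' Initial alignment before ICP
#'
#' Coarse alignment that places the moving model inside the basin of
#' attraction of iterative closest point. `"centroid"` translates the
#' moving model's vertex centroid onto the target's; `"centroid+pca"`
#' additionally aligns the principal axes of the vertex clouds, testing
#' all four proper-rotation sign combinations and keeping the candidate
#' with the lowest RMS vertex-to-surface distance; `"identity"` performs
#' no alignment.
#'
#' @param moving,target [triangle_mesh()] objects.
#' @param mode `"centroid"`, `"centroid+pca"`, or `"identity"`.
#' @param index optional prebuilt closest-point index of the target
#'   surface (internal use; rebuilt when `NULL`).
#' @return a [rigid_transform()] mapping moving into target coordinates.
#' @export
initial_align <- function(moving, target,
                          mode = c("centroid+pca", "centroid", "identity"),
                          index = NULL) {
  mode <- match.arg(mode)
  if (nrow(moving$vertices) == 0L || nrow(target$vertices) == 0L)
    stop("initial_align: empty mesh")
  if (mode == "identity") return(rigid_transform())
  cm <- mesh_centroid(moving)
  ct <- mesh_centroid(target)
  if (mode == "centroid")
    return(rigid_transform(diag(3), ct - cm))
  em <- principal_axes(moving$vertices)
  et <- principal_axes(target$vertices)
  if (is.null(em) || is.null(et)) {
    warning("degenerate inertia tensor; falling back to centroid alignment")
    return(rigid_transform(diag(3), ct - cm))
  }
  if (is.null(index)) index <- cpp_surface_index(target$vertices,
                                                 target$faces)
  # four proper sign combinations of the axis correspondence
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL
  best_obj <- Inf
  for (s in signs) {
    r <- et %*% diag(s) %*% t(em)
    if (det(r) < 0) next
    cand <- rigid_transform(r, ct - as.numeric(r %*% cm))
    d <- cpp_index_query(index,
                         transform_points(moving$vertices, cand))$distance
    obj <- sqrt(mean(d^2))
    if (obj < best_obj) {
      best_obj <- obj
      best <- cand
    }
  }
  best
}

# eigenvectors of the vertex covariance, ordered by decreasing variance,
# forced right-handed; NULL when the spectrum is degenerate
principal_axes <- function(v) {
  cv <- stats::cov(v)
  e <- eigen(cv, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values)) return(NULL)
  ax <- e$vectors
  if (det(ax) < 0) ax[, 3] <- -ax[, 3]
  ax
}

#' Rigid registration by iterative closest point
#'
#' Aligns a moving vertebra surface model onto a target model of the same
#' bone. Each iteration (a) finds, for every moving vertex, the closest
#' point on the target surface (point-to-surface correspondence) and (b)
#' solves the least-squares rigid update in closed form by the orthogonal
#' Procrustes (SVD/Kabsch) solution. The objective is the root mean
#' square of correspondence distances; iteration stops when its relative
#' change falls below `tolerance` or `max_iterations` is reached. The
#' algorithm is deterministic: no vertex sampling or randomization is
#' performed.
#'
#' @param moving,target [triangle_mesh()] objects; `moving` is registered
#'   onto `target`.
#' @param init initial [rigid_transform()], typically from
#'   [initial_align()]; defaults to centroid+principal-axes alignment.
#' @param max_iterations iteration cap (default 200).
#' @param tolerance relative objective-change stopping threshold
#'   (default 1e-6).
#' @param trim_quantile optional in (0, 1]; per iteration, only
#'   correspondences with distance at or below this quantile enter the
#'   rigid update (1 = no trimming, the default; same-bone models need
#'   none).
#' @return object of class `registration_result`: list with `transform`
#'   (moving to target), `objective_trace` (RMS mm per iteration),
#'   `iterations`, `converged`, and `final_report` (a
#'   [deviation_report()] of the transformed moving model against the
#'   target).
#' @export
icp_register <- function(moving, target, init = NULL, max_iterations = 200L,
                         tolerance = 1e-6, trim_quantile = 1) {
  stopifnot(max_iterations >= 1L, tolerance > 0,
            trim_quantile > 0, trim_quantile <= 1)
  if (any(!is.finite(moving$vertices)) || any(!is.finite(target$vertices)))
    stop("icp_register: non-finite vertex coordinates")
  index <- cpp_surface_index(target$vertices, target$faces)
  if (is.null(init)) init <- initial_align(moving, target, index = index)
  cur <- init
  pts0 <- moving$vertices
  trace <- numeric(0)
  converged <- FALSE
  prev_obj <- Inf
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    pts <- sweep(pts0 %*% t(cur$rotation), 2, cur$translation, "+")
    cp <- cpp_index_query(index, pts)
    d <- cp$distance
    obj <- sqrt(mean(d^2))
    trace <- c(trace, obj)
    if (is.finite(prev_obj) &&
        abs(prev_obj - obj) <= tolerance * max(prev_obj, 1e-8)) {
      converged <- TRUE
      break
    }
    prev_obj <- obj
    keep <- if (trim_quantile < 1)
      d <= stats::quantile(d, trim_quantile) else rep(TRUE, length(d))
    upd <- kabsch(pts[keep, , drop = FALSE],
                  cp$point[keep, , drop = FALSE])
    cur <- compose(upd, cur)
  }
  final_mesh <- apply_transform(moving, cur)
  final_d <- signed_distances(final_mesh, target)
  structure(list(transform = cur,
                 objective_trace = trace,
                 iterations = it,
                 converged = converged,
                 final_report = deviation_report(final_d,
                                                 level = moving$label)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: %d iterations, %s, final RMS %.5f mm\n",
              x$iterations,
              if (x$converged) "converged" else "not converged",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

# least-squares rigid transform mapping point set x onto y (Kabsch/SVD)
kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  h <- crossprod(sweep(x, 2, cx), sweep(y, 2, cy))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(r, cy - as.numeric(r %*% cx))
}

#' Serialize a registration result as JSON
#'
#' Stores the transform (row-major rotation + translation), the objective
#' trace, iteration count, and convergence flag.
#'
#' @param result a `registration_result` from [icp_register()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_registration_json <- function(result, path) {
  obj <- c(transform_to_list(result$transform),
           list(objective_trace_rms_mm = result$objective_trace,
                iterations = result$iterations,
                converged = result$converged))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
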