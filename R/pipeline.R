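#' Study configuration
#'
#' Bundles the settings of a registration/kinematics run: where the
#' meshes and landmark files live, registration parameters, the Euler
#' sequence and kinematics mode, output directory, and the global seed.
#' All settings are echoed verbatim into the run manifest.
#'
#' @param manifest path to a study manifest JSON (as written by
#'   [simulate_study()]), or `NULL` when `mesh_dir` conventions are used.
#' @param mesh_dir directory containing `<level>_<posture>.stl` meshes
#'   and `<level>_landmarks.csv` files (used when `manifest` is `NULL`).
#' @param out_dir output directory (created if missing).
#' @param init_mode initial alignment mode for [initial_align()].
#' @param tolerance,max_iterations ICP settings, see [icp_register()].
#' @param sequence Euler sequence for [decompose_rotation()].
#' @param mode kinematics mode, see [intervertebral_6dof()].
#' @param seed global seed.
#' @return object of class `study_config` (a named list).
#' @export
study_config <- function(manifest = NULL, mesh_dir = NULL,
                         out_dir = tempfile("spinekin_run_"),
                         init_mode = "centroid+pca", tolerance = 1e-6,
                         max_iterations = 200L, sequence = "yxz",
                         mode = "motion_from_neutral", seed = 1L) {
  if (is.null(manifest) && is.null(mesh_dir))
    stop("study_config: provide a manifest path or a mesh_dir")
  if (!is.null(manifest) && !file.exists(manifest))
    stop("study_config: manifest not found: ", manifest)
  if (!is.null(mesh_dir) && is.null(manifest) && !dir.exists(mesh_dir))
    stop("study_config: mesh_dir not found: ", mesh_dir)
  structure(list(manifest = manifest, mesh_dir = mesh_dir,
                 out_dir = out_dir, init_mode = init_mode,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 sequence = sequence, mode = mode, seed = as.integer(seed)),
            class = "study_config")
}

#' Write a synthetic multi-posture study to disk
#'
#' Generates the seven synthetic vertebrae, stacks them into a neutral
#' spine, and writes: per-level neutral meshes and landmark CSVs; for
#' every non-neutral posture of the scenario, an independently remeshed
#' and noise-perturbed copy moved by the ground-truth transform; the
#' ground-truth transforms; and a manifest JSON tying everything
#' together. Per-level validation pairs (the neutral mesh and an
#' independently remeshed/perturbed copy of it) are included for
#' model-accuracy runs.
#'
#' @param dir output directory.
#' @param scenario a [make_scenario()] result.
#' @param noise_sigma surface noise (mm) applied to the remeshed copies.
#' @param remesh_factor face-count ratio for the remeshed copies.
#' @param subdivisions mesh resolution, see [vertebra_spec()].
#' @param seed global seed; per-level/per-posture seeds are derived
#'   deterministically from it.
#' @param format mesh file format (`"STL"` binary or `"PLY"`).
#' @return the manifest (a list), invisibly; written to
#'   `file.path(dir, "manifest.json")`.
#' @export
simulate_study <- function(dir, scenario = make_scenario("ar"),
                           noise_sigma = 0.2, remesh_factor = 4,
                           subdivisions = 4L, seed = 1L,
                           format = c("STL", "PLY")) {
  format <- match.arg(format)
  stopifnot(inherits(scenario, "motion_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- tolower(format)
  manifest <- list(seed = seed, noise_sigma = noise_sigma,
                   remesh_factor = remesh_factor,
                   postures = scenario$postures, levels = scenario$levels,
                   scenario = scenario$name, files = list(),
                   transforms = list(), injected = scenario$injected)
  for (i in seq_along(scenario$levels)) {
    lev <- scenario$levels[i]
    spec <- vertebra_spec(lev, subdivisions = subdivisions)
    base <- generate_vertebra(spec)
    off <- scenario$mesh_offsets[[lev]]
    neutral <- base
    neutral$vertices <- sweep(neutral$vertices, 2, off, "+")
    lm <- synthetic_landmarks(spec)
    for (nm in c("origin_candidate", "superior_reference",
                 "left_reference", "right_reference"))
      lm[[nm]] <- lm[[nm]] + off
    npath <- file.path(dir, sprintf("%s_neutral.%s", lev, ext))
    write_mesh(neutral, npath, format)
    lpath <- file.path(dir, sprintf("%s_landmarks.csv", lev))
    write_landmarks(lm, lpath)
    # validation pair: an independently segmented copy of the neutral bone
    vseed <- seed * 1000L + i
    vcopy <- perturb_mesh(neutral, noise_sigma, remesh_factor, vseed)
    vpath <- file.path(dir, sprintf("%s_validation.%s", lev, ext))
    write_mesh(vcopy, vpath, format)
    files <- list(neutral = npath, landmarks = lpath, validation = vpath)
    tlist <- list()
    for (p in setdiff(scenario$postures, "neutral")) {
      pseed <- seed * 1000L + i * 10L +
        match(p, scenario$postures)
      moved <- perturb_mesh(neutral, noise_sigma, remesh_factor, pseed)
      tgt <- scenario$transforms[[lev]][[p]]
      moved <- apply_transform(moved, tgt)
      moved$posture <- p
      ppath <- file.path(dir, sprintf("%s_%s.%s", lev, p, ext))
      write_mesh(moved, ppath, format)
      files[[p]] <- ppath
      tlist[[p]] <- transform_to_list(tgt)
    }
    manifest$files[[lev]] <- files
    manifest$transforms[[lev]] <- tlist
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(manifest)
}

read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = TRUE)
}

#' Model-accuracy validation run (phase 1)
#'
#' For every vertebra level with a paired model set (e.g. CT-like and
#' CBCT-like segmentations of the same bone), registers the pair by ICP
#' and reports the signed-deviation statistics of the registered models
#' as one CSV row per level. Missing levels are skipped with a warning.
#'
#' @param config a [study_config()]; its manifest (or mesh directory)
#'   must provide, per level, a `neutral` and a `validation` mesh.
#' @return data.frame of per-level deviation statistics (also written to
#'   `validation_accuracy.csv` in the output directory).
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- study_files(config)
  reports <- list()
  for (lev in names(files)) {
    fl <- files[[lev]]
    if (is.null(fl$neutral) || is.null(fl$validation) ||
        !file.exists(fl$neutral) || !file.exists(fl$validation)) {
      warning("run_validation: level ", lev, " has no model pair; skipped")
      next
    }
    target <- read_mesh(fl$validation, label = lev)
    moving <- read_mesh(fl$neutral, label = lev)
    res <- icp_register(moving, target,
                        init = initial_align(moving, target,
                                             config$init_mode),
                        max_iterations = config$max_iterations,
                        tolerance = config$tolerance)
    reports[[lev]] <- res$final_report
  }
  if (!length(reports)) stop("run_validation: no registrable level pairs")
  tab <- write_deviation_csv(reports,
                             file.path(config$out_dir,
                                       "validation_accuracy.csv"))
  write_run_manifest(config, "validation")
  tab
}

#' Registration and 6-DOF kinematics run (phases 2-3)
#'
#' For every level: registers the neutral model onto each end-position
#' model (the end-position model is the fixed target), writes the
#' recovered transforms as JSON and a per-level, per-posture registration
#' accuracy CSV; then builds the anatomic frames from the neutral
#' landmark files, carries them through the recovered transforms, and
#' writes the 6-DOF intervertebral kinematics CSV for every adjacent
#' level pair and posture. A registration that fails to converge is
#' flagged in the accuracy table and its postures are still reported;
#' a missing neutral model is a fatal error.
#'
#' @param config a [study_config()].
#' @return list with `kinematics` (data.frame), `accuracy` (data.frame),
#'   and `transforms` (nested list), all also written to the output
#'   directory.
#' @export
run_kinematics <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- study_files(config)
  levels <- names(files)
  postures <- setdiff(unique(unlist(lapply(files, function(fl)
    intersect(names(fl), POSTURES)))), "neutral")
  frames <- list()
  transforms <- list()
  acc <- list()
  tdir <- file.path(config$out_dir, "transforms")
  dir.create(tdir, showWarnings = FALSE)
  for (lev in levels) {
    fl <- files[[lev]]
    if (is.null(fl$neutral) || !file.exists(fl$neutral))
      stop("run_kinematics: missing neutral model for level ", lev)
    if (is.null(fl$landmarks) || !file.exists(fl$landmarks))
      stop("run_kinematics: missing landmark file for level ", lev)
    neutral <- read_mesh(fl$neutral, label = lev, posture = "neutral")
    frames[[lev]] <- build_frame(read_landmarks(fl$landmarks, level = lev))
    transforms[[lev]] <- list(neutral = rigid_transform())
    for (p in postures) {
      if (is.null(fl[[p]]) || !file.exists(fl[[p]])) next
      target <- read_mesh(fl[[p]], label = lev, posture = p)
      res <- icp_register(neutral, target,
                          init = initial_align(neutral, target,
                                               config$init_mode),
                          max_iterations = config$max_iterations,
                          tolerance = config$tolerance)
      transforms[[lev]][[p]] <- res$transform
      write_registration_json(res,
        file.path(tdir, sprintf("%s_%s.json", lev, p)))
      row <- res$final_report
      row$posture <- p
      row$converged <- res$converged
      row$iterations <- res$iterations
      acc[[length(acc) + 1L]] <- row
      if (!res$converged)
        warning("run_kinematics: registration of ", lev, " at ", p,
                " did not converge; row flagged")
    }
  }
  acc_tab <- do.call(rbind, lapply(acc, as.data.frame))
  write.csv(acc_tab, file.path(config$out_dir,
                               "registration_accuracy.csv"),
            row.names = FALSE)
  kin <- list()
  for (i in seq_len(length(levels) - 1L)) {
    pair <- paste0(levels[i], "-", levels[i + 1L])
    for (p in c("neutral", postures)) {
      ok <- !is.null(transforms[[levels[i]]][[p]]) &&
        !is.null(transforms[[levels[i + 1L]]][[p]])
      if (!ok) next
      kin[[length(kin) + 1L]] <-
        intervertebral_6dof(frames, transforms, pair, p,
                            mode = config$mode,
                            sequence = config$sequence)
    }
  }
  kin_tab <- write_kinematics_csv(kin,
    file.path(config$out_dir, "kinematics.csv"))
  write_run_manifest(config, "kinematics")
  list(kinematics = kin_tab, accuracy = acc_tab, transforms = transforms)
}

# resolve the per-level file lists from a manifest or directory layout
study_files <- function(config) {
  if (!is.null(config$manifest)) {
    man <- read_manifest(config$manifest)
    base <- dirname(config$manifest)
    files <- lapply(man$files, function(fl) {
      lapply(fl, function(p)
        if (file.exists(p)) p else file.path(base, basename(p)))
    })
    return(files)
  }
  files <- list()
  for (lev in LEVELS) {
    fl <- list()
    for (p in POSTURES) {
      cand <- Sys.glob(file.path(config$mesh_dir,
                                 sprintf("%s_%s.*", lev, p)))
      cand <- cand[grepl("\\.(stl|ply)$", tolower(cand))]
      if (length(cand)) fl[[p]] <- cand[1]
    }
    vcand <- Sys.glob(file.path(config$mesh_dir,
                                sprintf("%s_validation.*", lev)))
    vcand <- vcand[grepl("\\.(stl|ply)$", tolower(vcand))]
    if (length(vcand)) fl$validation <- vcand[1]
    lpath <- file.path(config$mesh_dir, sprintf("%s_landmarks.csv", lev))
    if (file.exists(lpath)) fl$landmarks <- lpath
    if (length(fl)) files[[lev]] <- fl
  }
  if (!length(files))
    stop("no per-level mesh files found in ", config$mesh_dir)
  files
}

write_run_manifest <- function(config, phase) {
  obj <- c(unclass(config),
           list(phase = phase,
                package_version =
                  as.character(utils::packageVersion("spinekin")),
                timestamp = format(Sys.time(), tz = "UTC",
                                   usetz = TRUE)))
  jsonlite::write_json(obj, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(obj)
}
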