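#' Pipeline configuration
#'
#' Assembles (or loads from YAML) the configuration of the end-to-end run:
#' synthetic capture settings, estimation parameters, kinematic conventions
#' and export settings. Unknown keys are rejected.
#'
#' @param path optional YAML file; its keys override the defaults.
#' @param seed overrides the seed from the file/defaults when non-`NULL`.
#' @return Object of class `pipeline_config`: list with `sim`
#'   (a [motion_config()]), `dims` (a [body_dimensions()]), `est`
#'   (an [estimation_params()]), `global_up`, and `seed`.
#' @export
pipeline_config <- function(path = NULL, seed = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) .stopf("config file not found: %s", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  known <- c("seed", "sim", "dims", "est", "global_up")
  unk <- setdiff(names(raw), known)
  if (length(unk))
    .stopf("unknown config keys: %s", paste(unk, collapse = ", "))
  take <- function(block, fn) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      .stopf("unknown %s config keys: %s", block, paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  sim <- take("sim", motion_config)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  else if (!is.null(raw$seed)) sim$seed <- as.integer(raw$seed)
  structure(list(sim = sim,
                 dims = take("dims", body_dimensions),
                 est = take("est", estimation_params),
                 global_up = if (is.null(raw$global_up)) c(0, -1, 0)
                             else as.numeric(raw$global_up),
                 seed = sim$seed),
            class = "pipeline_config")
}

#' Simulate a capture session to disk
#'
#' Generates a synthetic motion, corrupts it with the configured tracker
#' noise, and writes the artifacts of a capture: the corrupted skeleton CSV
#' (what a tracker would have recorded), per-frame per-limb PLY point
#' clouds (`frame{N}_{label}.ply`), the clean skeleton CSV and the
#' ground-truth angle CSV.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the generated `skel_motion`, the corrupted
#'   sequence and the file paths.
#' @export
simulate_capture <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- generate_motion(config$sim, config$dims)
  corr <- corrupt_sequence(gt$clean, config$sim)
  paths <- list(
    skeleton = file.path(out_dir, "skeleton.csv"),
    clean = file.path(out_dir, "skeleton_clean.csv"),
    truth = file.path(out_dir, "angles_truth.csv")
  )
  write_skeleton(corr, paths$skeleton)
  write_skeleton(gt$clean, paths$clean)
  gta <- structure(list(angles = gt$angles, frame_rate = config$sim$frame_rate,
                        global_up = config$global_up), class = "joint_angles")
  write_angles(gta, paths$truth)
  cloud_dir <- file.path(out_dir, "clouds")
  dir.create(cloud_dir, showWarnings = FALSE)
  for (f in gt$clean$frames) {
    cl <- sample_point_clouds(f, config$sim)
    for (lab in names(cl))
      write_ply(cl[[lab]],
                file.path(cloud_dir, sprintf("frame%d_%s.ply",
                                             f$frame_index, lab)))
  }
  paths$clouds <- cloud_dir
  invisible(list(motion = gt, corrupted = corr, paths = paths))
}

#' Load per-frame point clouds from a directory of PLY files
#'
#' Expects the `frame{N}_{label}.ply` naming convention of
#' [simulate_capture()].
#'
#' @param dir directory of PLY files.
#' @param sequence the `skel_sequence` the clouds accompany (alignment by
#'   frame index).
#' @return List parallel to `sequence$frames` of named `pc_segment` lists.
#' @export
load_point_cloud_dir <- function(dir, sequence) {
  files <- list.files(dir, pattern = "^frame[0-9]+_.+\\.ply$")
  if (!length(files)) .stopf("no frame{N}_{label}.ply files in %s", dir)
  fidx <- as.integer(sub("^frame([0-9]+)_.*$", "\\1", files))
  lab <- sub("^frame[0-9]+_(.+)\\.ply$", "\\1", files)
  lapply(sequence$frames, function(f) {
    sel <- which(fidx == f$frame_index)
    if (!length(sel)) return(NULL)
    cl <- lapply(sel, function(k) read_ply(file.path(dir, files[k]), lab[k]))
    stats::setNames(cl, lab[sel])
  })
}

#' Run the full pipeline: simulate, repair, extract angles, export
#'
#' Composes the whole post-processing stack on a synthetic capture:
#' generate ground-truth motion, corrupt it with tracker noise and dropout,
#' repair the corrupted stream from the per-limb point clouds, extract the
#' anatomical joint-angle series, bridge undefined gaps, and export a BVH
#' animation plus CSV artifacts and a machine-readable JSON run report.
#' Deterministic given the configured seed.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param out_dir output directory.
#' @return Object of class `skel_pipeline`: list with the fitted objects
#'   (`motion`, `corrupted`, `fit`, `angles`) and `paths` of all artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- generate_motion(config$sim, config$dims)
  corr <- corrupt_sequence(gt$clean, config$sim)
  clouds <- lapply(gt$clean$frames, sample_point_clouds, config = config$sim)
  fit <- skeleton_repair(corr, clouds, config$est)
  ang <- joint_angles(fit$sequence, config$global_up)
  smooth <- interpolate_angles(ang)

  paths <- list(raw = file.path(out_dir, "skeleton_raw.csv"),
                corrected = file.path(out_dir, "skeleton_corrected.csv"),
                angles = file.path(out_dir, "angles.csv"),
                bvh = file.path(out_dir, "motion.bvh"),
                log = file.path(out_dir, "repairs.csv"),
                report = file.path(out_dir, "report.json"))
  write_skeleton(corr, paths$raw)
  write_skeleton(fit$sequence, paths$corrected)
  write_angles(ang, paths$angles)
  # pelvis trajectory of the repaired stream: midpoint of the two hips
  rootp <- t(vapply(fit$sequence$frames, function(f)
    (f$positions[9L, ] + f$positions[12L, ]) / 2, numeric(3L)))
  model <- kinematic_model(config$dims)
  write_bvh(smooth, paths$bvh, model, frame_time = 1 / smooth$frame_rate,
            root_positions = rootp, na_action = "zero")
  write_repair_log(fit, paths$log)

  acts <- table(factor(fit$log$action,
                       c("kept", "repaired", "fallback", "passthrough")))
  report <- list(
    package = "skelkit",
    version = as.character(utils::packageVersion("skelkit")),
    seed = config$seed,
    n_frames = config$sim$n_frames,
    frame_rate = config$sim$frame_rate,
    reference_frame = fit$reference_frame,
    joints_kept = unname(acts[["kept"]]),
    joints_repaired = unname(acts[["repaired"]]),
    joints_fallback = unname(acts[["fallback"]]),
    injected_dropouts = sum(attr(corr, "dropout")),
    estimation = unclass(config$est),
    noise = list(depth_sd = config$sim$depth_noise_sd,
                 xy_sd = config$sim$xy_noise_sd,
                 dropout_prob = config$sim$dropout_prob)
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(list(motion = gt, corrupted = corr, fit = fit, angles = ang,
                 paths = paths, config = config),
            class = "skel_pipeline")
}

#' @export
print.skel_pipeline <- function(x, ...) {
  cat("pipeline run:\n")
  print(x$fit)
  cat("artifacts:\n")
  for (p in unlist(x$paths)) cat("  ", p, "\n", sep = "")
  invisible(x)
}
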