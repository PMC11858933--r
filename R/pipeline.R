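# End-to-end pipeline: triangulate -> select cameras -> filter -> scale ->
# IK -> evaluate, driven by a JSON config, plus the simulator's on-disk
# output layout.

pipeline_schema <- function() {
  list(
    seed = 0L,
    input = list(rig = NULL, tracks2d = NULL, reference_c3d = NULL,
                 static_c3d = NULL),
    thresholds = list(reproj_mm = 10, anat_mm = 5),
    min_confidence = 0.5,
    filter = list(cutoff = 6),
    scale = list(window_s = 5),
    ik = list(max_iter = 50, tol = 1e-6),
    evaluate = list(max_lag_s = 2),
    hand = "right",
    output = list(dir = NULL))
}

validate_config <- function(config, schema = pipeline_schema(), path = "") {
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]])) && is.list(config[[k]]))
      validate_config(config[[k]], schema[[k]], paste0(path, k, "."))
  }
  utils::modifyList(schema, config)
}

#' Run the full processing pipeline from a config
#'
#' Stages: load calibration and per-camera 2D tracks, select the optimal
#' camera subset, triangulate, low-pass filter, scale the skeleton (from a
#' static trial if given), run IK, and — when a reference C3D is supplied —
#' compare against it. Outputs (C3D, TRC, angle CSV, JSON report and a
#' MANIFEST) are written to the configured directory. Deterministic given
#' the config and seed.
#'
#' @param config a list, or the path of a JSON config file. Keys:
#'   `seed`; `input` (`rig`, `tracks2d` — directory or vector of CSV paths,
#'   `reference_c3d`, `static_c3d`); `thresholds` (`reproj_mm`, `anat_mm`);
#'   `min_confidence`; `filter` (`cutoff`); `scale` (`window_s`); `ik`
#'   (`max_iter`, `tol`); `evaluate` (`max_lag_s`); `hand`; `output`
#'   (`dir`). Unknown keys raise a schema error before any computation.
#' @param verbose log stage progress (default TRUE).
#' @return invisibly, a list with the selection result, the triangulated
#'   and filtered tracks, the IK fit, the trial comparison (or NULL) and
#'   the report list.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  cfg <- validate_config(config)
  if (is.null(cfg$input$rig) || is.null(cfg$input$tracks2d))
    stop("config must provide input$rig and input$tracks2d")
  log <- function(...) if (verbose) message(sprintf(...))
  set.seed(cfg$seed)
  manifest <- character(0)
  note <- function(x) manifest <<- c(manifest, x)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  rig <- stage("load_rig", load_rig(cfg$input$rig))
  log("loaded rig with %d cameras", length(rig$cameras))
  paths <- cfg$input$tracks2d
  if (length(paths) == 1 && dir.exists(paths)) {
    dir <- paths
    paths <- list.files(dir, pattern = "_2d\\.csv$", full.names = TRUE)
    if (!length(paths))
      paths <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  }
  tracks <- stage("load_tracks", lapply(paths, read_track2d_csv))
  log("loaded %d 2D tracks: %s", length(tracks),
      paste(vapply(tracks, `[[`, character(1), "camera_name"), collapse = ", "))

  skeleton <- build_default_skeleton(cfg$hand)
  sel <- stage("select_cameras",
               select_subset(tracks, rig, skeleton,
                             thresholds = cfg$thresholds,
                             min_confidence = cfg$min_confidence))
  log("selected cameras {%s} (%s); worst reprojection %.2f mm, anatomical %.2f mm; thresholds %.1f/%.1f mm",
      paste(sel$chosen$subset, collapse = ","), sel$reason,
      max(sel$chosen$reproj_rmse_mm), sel$chosen$anatomical_mm,
      cfg$thresholds$reproj_mm, cfg$thresholds$anat_mm)
  note(sprintf("subset: %s (%s)", paste(sel$chosen$subset, collapse = ","),
               sel$reason))

  t3 <- stage("triangulate",
              triangulate_tracks(tracks, rig, sel$chosen$subset,
                                 cfg$min_confidence))
  t3f <- stage("filter", lowpass(t3, cutoff = cfg$filter$cutoff))
  log("triangulated %d frames (%.1f%% visible), filtered at %g Hz",
      n_frames(t3), 100 * mean(t3$visible), cfg$filter$cutoff)

  static_track <- if (!is.null(cfg$input$static_c3d))
    stage("load_static", read_c3d(cfg$input$static_c3d)) else NULL
  skel <- if (!is.null(static_track))
    stage("scale", scale_skeleton(skeleton, static_track, cfg$scale$window_s))
  else skeleton
  ik <- stage("ik", inverse_kinematics(t3f, skel,
                                       max_iter = cfg$ik$max_iter,
                                       tol = cfg$ik$tol))
  log("IK: %d/%d frames converged", sum(ik$converged, na.rm = TRUE),
      length(ik$converged))

  comparison <- NULL
  if (!is.null(cfg$input$reference_c3d)) {
    ref <- stage("load_reference", read_c3d(cfg$input$reference_c3d))
    comparison <- stage("evaluate",
                        compare_trial(ref, t3f, skeleton,
                                      static_track = static_track,
                                      config = list(window_s = cfg$scale$window_s,
                                                    max_lag_s = cfg$evaluate$max_lag_s,
                                                    scale = !is.null(static_track))))
    log("evaluation: mean joint-angle RMSE %.2f deg over %d joints",
        comparison$mean_rmse, sum(comparison$included))
  }

  report <- list(
    seed = cfg$seed,
    chosen_subset = sel$chosen$subset,
    selection_reason = sel$reason,
    reprojection_rmse_px = as.list(sel$chosen$reproj_rmse_px),
    reprojection_rmse_mm = as.list(sel$chosen$reproj_rmse_mm),
    anatomical_error_mm = sel$chosen$anatomical_mm,
    ik_frames_converged = sum(ik$converged, na.rm = TRUE),
    mean_rmse_deg = if (!is.null(comparison)) comparison$mean_rmse else NULL)

  out <- cfg$output$dir
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stage("export", {
      write_c3d(t3f, file.path(out, "triangulated.c3d"))
      write_trc(t3f, file.path(out, "triangulated.trc"))
      write_angles_csv(ik$angles, file.path(out, "joint_angles.csv"))
      jsonlite::write_json(report, file.path(out, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
      if (!is.null(comparison))
        write_trial_report(comparison, file.path(out, "comparison.csv"),
                           file.path(out, "comparison.json"))
      note("triangulated.c3d"); note("triangulated.trc")
      note("joint_angles.csv"); note("report.json")
      if (!is.null(comparison)) { note("comparison.csv"); note("comparison.json") }
      writeLines(manifest, file.path(out, "MANIFEST"))
    })
    log("outputs written to %s", out)
  }
  invisible(list(selection = sel, track3d = t3, filtered = t3f, ik = ik,
                 comparison = comparison, report = report))
}

#' Write a simulated trial to a directory
#'
#' Produces the on-disk layout the pipeline consumes: the calibration file,
#' one 2D CSV per camera, the ground-truth C3D (at the reference rate) and
#' the ground-truth joint-angle CSV.
#'
#' @param cfg a [synthetic_task_config()].
#' @param dir output directory (created if needed).
#' @param rig a [camera_rig()].
#' @param skeleton hand skeleton.
#' @param ref_fs reference-track rate in Hz.
#' @return invisibly, the [simulate_trial()] result.
#' @export
simulate_to_dir <- function(cfg, dir, rig = make_rig(4),
                            skeleton = build_default_skeleton(),
                            ref_fs = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_trial(cfg, rig, skeleton, ref_fs = ref_fs)
  save_rig(rig, file.path(dir, "calibration.json"))
  for (v in sim$views)
    write_track2d_csv(v, file.path(dir, paste0(v$camera_name, "_2d.csv")))
  write_c3d(sim$reference, file.path(dir, "ground_truth.c3d"))
  write_angles_csv(sim$truth$angles, file.path(dir, "ground_truth_angles.csv"))
  invisible(sim)
}
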