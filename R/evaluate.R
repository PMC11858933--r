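# Comparison metrics between motion-capture methods: occlusion rates,
# occlusion-gated per-joint angle RMSE (joints whose central landmark is
# occluded for more than 50% of the trial are excluded entirely), range of
# motion, and the per-trial orchestration.

#' Per-landmark occlusion rates
#'
#' Fraction of frames in which each landmark is not observed.
#' Interpolation-flagged (gap-filled) samples count as occluded, since they
#' were not directly measured.
#'
#' @param track a [track3d()].
#' @return named numeric vector of fractions in \[0, 1\], with attribute
#'   `"mean"` (grand mean over landmarks).
#' @export
occlusion_rates <- function(track) {
  if (n_frames(track) < 1) stop("track has no frames")
  occ <- colMeans(!track$visible | track$interpolated)
  names(occ) <- track$landmark_names
  attr(occ, "mean") <- mean(occ)
  occ
}

#' Occlusion-gated per-joint angle RMSE between two series
#'
#' Per joint, the RMSE over frames valid in both series. Joints whose
#' occlusion fraction exceeds 0.5 (strictly) are excluded entirely (NaN);
#' the trial mean is taken over included joints only. Included joints with
#' zero jointly-valid frames are excluded with status `"no_support"`.
#'
#' @param ref,test [joint_angle_series()] on a common rate and time grid,
#'   same joint order.
#' @param occlusion per-joint occlusion fractions (default all 0).
#' @return list with `per_joint_rmse` (degrees, NaN when excluded),
#'   `included` (logical), `status` (one of `included`, `occluded`,
#'   `no_support`), `n_frames_compared`, and `mean_rmse`.
#' @export
joint_angle_rmse <- function(ref, test, occlusion = NULL) {
  if (!identical(ref$joint_names, test$joint_names))
    stop("joint names differ between series")
  if (abs(ref$fs - test$fs) > 1e-9)
    stop("series must share a sampling rate (resample first)")
  J <- length(ref$joint_names)
  if (is.null(occlusion)) occlusion <- numeric(J)
  stopifnot(length(occlusion) == J)
  n <- min(nrow(ref$angles), nrow(test$angles))
  rmse_j <- rep(NaN, J)
  nfrm <- integer(J)
  status <- character(J)
  for (j in seq_len(J)) {
    if (occlusion[j] > 0.5) { status[j] <- "occluded"; next }
    ok <- ref$valid[seq_len(n), j] & test$valid[seq_len(n), j]
    nfrm[j] <- sum(ok)
    if (!any(ok)) { status[j] <- "no_support"; next }
    d <- ref$angles[seq_len(n), j][ok] - test$angles[seq_len(n), j][ok]
    rmse_j[j] <- rmse(d)
    status[j] <- "included"
  }
  included <- status == "included"
  names(rmse_j) <- names(nfrm) <- names(status) <- ref$joint_names
  list(per_joint_rmse = rmse_j,
       included = included,
       status = status,
       n_frames_compared = nfrm,
       mean_rmse = if (any(included)) mean(rmse_j[included]) else NaN)
}

#' Range of motion per joint
#'
#' Max minus min of each joint angle over its valid frames, plus the mean
#' over joints with at least one valid frame.
#'
#' @param series a [joint_angle_series()].
#' @return named numeric vector of per-joint RoM in degrees (NaN where no
#'   valid frame), with attribute `"mean"`.
#' @export
range_of_motion <- function(series) {
  rom <- apply(series$angles, 2, function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) NaN else max(x) - min(x)
  })
  names(rom) <- series$joint_names
  attr(rom, "mean") <- mean(rom[is.finite(rom)])
  rom
}

# The landmark at each named joint's center, in skeleton landmark indices.
joint_center_landmarks <- function(skeleton) {
  stats::setNames(skeleton$joints$landmark, skeleton$joints$name)
}

# Mean finger-MCP flexion over valid frames, for gesture-based alignment.
mean_mcp_flexion <- function(series) {
  mcp <- match(c("2mcp", "3mcp", "4mcp", "5mcp"), series$joint_names)
  mcp <- mcp[!is.na(mcp)]
  rowMeans(series$angles[, mcp, drop = FALSE], na.rm = TRUE)
}

# Linear resampling of a joint-angle series (validity gated like tracks).
resample_angles <- function(series, fs_out) {
  n <- nrow(series$angles)
  t_src <- series$t0 + (seq_len(n) - 1) / series$fs
  span <- t_src[n] - t_src[1]
  n_out <- floor(span * fs_out + 1e-9) + 1
  t_out <- series$t0 + (seq_len(n_out) - 1) / fs_out
  lo <- pmin(pmax(findInterval(t_out, t_src, rightmost.closed = TRUE), 1L), n - 1L)
  hi <- lo + 1L
  w <- (t_out - t_src[lo]) / (t_src[hi] - t_src[lo])
  exact_lo <- abs(w) < 1e-9; exact_hi <- abs(w - 1) < 1e-9
  J <- ncol(series$angles)
  ang <- matrix(NaN, n_out, J)
  val <- matrix(FALSE, n_out, J)
  for (j in seq_len(J)) {
    vj <- series$valid[, j]
    val[, j] <- ifelse(exact_lo, vj[lo], ifelse(exact_hi, vj[hi], vj[lo] & vj[hi]))
    x <- series$angles[, j]
    ang[, j] <- (1 - w) * x[lo] + w * x[hi]
    ang[exact_lo, j] <- x[lo[exact_lo]]
    ang[exact_hi, j] <- x[hi[exact_hi]]
  }
  joint_angle_series(ang, joint_names = series$joint_names, valid = val,
                     fs = fs_out, t0 = series$t0)
}

# Shift a series by an integer number of frames (positive lag = series is
# delayed, so drop its first `lag` frames).
shift_angles <- function(series, lag) {
  n <- nrow(series$angles)
  idx <- if (lag >= 0) (lag + 1):n else 1:(n + lag)
  joint_angle_series(series$angles[idx, , drop = FALSE],
                     joint_names = series$joint_names,
                     valid = series$valid[idx, , drop = FALSE],
                     fs = series$fs, t0 = series$t0)
}

#' Compare a markerless trial against a marker-based reference
#'
#' Full per-trial orchestration: skeleton scaling (from a static trial if
#' provided, else from the first seconds of the reference), weighted IK on
#' both tracks, resampling of the joint-angle series to the lower of the two
#' rates, cross-correlation lag alignment on the mean MCP flexion, then the
#' occlusion-gated joint-angle RMSE, range of motion and occlusion rates.
#'
#' @param ref_track reference [track3d()] (e.g. marker-based, possibly with
#'   occlusions).
#' @param test_track test [track3d()] (e.g. triangulated markerless).
#' @param skeleton hand skeleton template.
#' @param static_track optional static-trial [track3d()] for scaling.
#' @param config list of options: `window_s` (scaling window, default 5),
#'   `max_lag_s` (default 2), `ik_weights`, `scale` (set FALSE to skip
#'   scaling).
#' @return an object of class `trial_comparison`.
#' @export
compare_trial <- function(ref_track, test_track, skeleton,
                          static_track = NULL, config = list()) {
  cfg <- utils::modifyList(
    list(window_s = 5, max_lag_s = 2, ik_weights = NULL, scale = TRUE),
    config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (n_frames(ref_track) < 1 || n_frames(test_track) < 1)
    stop("both tracks must be nonempty")
  skel <- if (isTRUE(cfg$scale)) {
    st <- if (!is.null(static_track)) static_track else ref_track
    stage("scale", scale_skeleton(skeleton, st, window_s = cfg$window_s))
  } else skeleton
  w <- if (is.null(cfg$ik_weights)) default_ik_weights(skel) else cfg$ik_weights
  occl_ref <- stage("occlusion", occlusion_rates(ref_track))
  ik_ref <- stage("ik_reference", inverse_kinematics(ref_track, skel, weights = w))
  ik_test <- stage("ik_test", inverse_kinematics(test_track, skel, weights = w))
  fs_cmp <- min(ref_track$fs, test_track$fs)
  ang_ref <- if (ref_track$fs > fs_cmp) resample_angles(ik_ref$angles, fs_cmp)
             else ik_ref$angles
  ang_test <- if (test_track$fs > fs_cmp) resample_angles(ik_test$angles, fs_cmp)
              else ik_test$angles
  lag <- stage("align", tryCatch(
    as.integer(estimate_lag(mean_mcp_flexion(ang_ref), mean_mcp_flexion(ang_test),
                            fs_cmp, cfg$max_lag_s)),
    error = function(e) {
      if (grepl("no signal", conditionMessage(e))) 0L else stop(e)
    }))
  if (lag > 0) ang_test <- shift_angles(ang_test, lag)
  if (lag < 0) ang_ref <- shift_angles(ang_ref, -lag)
  centers <- joint_center_landmarks(skel)
  occl_joint <- occl_ref[match(skel$landmark_names[centers],
                               names(occl_ref))]
  cmp <- stage("rmse", joint_angle_rmse(ang_ref, ang_test, occl_joint))
  structure(
    list(per_joint_rmse = cmp$per_joint_rmse,
         included = cmp$included,
         status = cmp$status,
         n_frames_compared = cmp$n_frames_compared,
         mean_rmse = cmp$mean_rmse,
         per_joint_rom_ref = range_of_motion(ang_ref),
         per_joint_rom_test = range_of_motion(ang_test),
         occlusion_rate = occl_ref,
         occlusion_per_joint = stats::setNames(occl_joint, skel$joints$name),
         lag_frames = lag,
         ik_ref = ik_ref, ik_test = ik_test,
         skeleton = skel),
    class = "trial_comparison")
}

#' @export
print.trial_comparison <- function(x, ...) {
  cat(sprintf("<trial_comparison> mean joint-angle RMSE %.2f deg over %d/%d joints; mean occlusion %.1f%%; lag %d frames\n",
              x$mean_rmse, sum(x$included), length(x$included),
              100 * attr(x$occlusion_rate, "mean"), x$lag_frames))
  invisible(x)
}

#' @export
summary.trial_comparison <- function(object, ...) {
  data.frame(joint = names(object$per_joint_rmse),
             rmse_deg = as.numeric(object$per_joint_rmse),
             included = object$included,
             status = as.character(object$status),
             n_frames = as.integer(object$n_frames_compared),
             rom_ref_deg = as.numeric(object$per_joint_rom_ref),
             rom_test_deg = as.numeric(object$per_joint_rom_test),
             occlusion = as.numeric(object$occlusion_per_joint),
             row.names = NULL)
}

#' Write a trial comparison report
#'
#' Writes a per-joint CSV table and a JSON summary.
#'
#' @param comparison a [compare_trial()] result.
#' @param csv_path,json_path output paths (NULL to skip either).
#' @return invisibly, the summary list written to JSON.
#' @export
write_trial_report <- function(comparison, csv_path = NULL, json_path = NULL) {
  tab <- summary(comparison)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  rep <- list(mean_rmse_deg = comparison$mean_rmse,
              n_joints_included = sum(comparison$included),
              mean_occlusion = attr(comparison$occlusion_rate, "mean"),
              mean_rom_ref_deg = attr(comparison$per_joint_rom_ref, "mean"),
              mean_rom_test_deg = attr(comparison$per_joint_rom_test, "mean"),
              lag_frames = comparison$lag_frames,
              per_joint = tab)
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE, na = "null")
  invisible(rep)
}
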