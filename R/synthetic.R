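# Synthetic articulated hand motion and virtual camera rigs: the fixture
# engine for validating every pipeline stage without recorded data.
#
# Motions are built from raised-cosine DOF pulses (C1-smooth, band-limited
# well below the 6 Hz filter cutoff at the default repetition rates). The
# five task presets mirror the experimental protocol: static hold, piano
# (sequential per-finger flexions ordered pinky to thumb), simultaneous
# full flexion, relax-then-hyperextend, and a ball transport task (grasp
# posture plus global translation).

#' Configuration of a synthetic task
#'
#' @param task one of `"static"`, `"piano"`, `"flexion"`, `"extension"`,
#'   `"ball"`.
#' @param n_reps number of movement repetitions (default 10).
#' @param fs sampling rate in Hz (default 30).
#' @param duration_s trial duration; default `n_reps` times the task's
#'   repetition period (2 s; 10 s for static).
#' @param amplitudes named list of peak joint excursions in degrees:
#'   `base`, `middle`, `distal` (defaults 80, 100, 70 for flexion-type
#'   tasks).
#' @param noise_px Gaussian pixel noise s.d. applied when rendering.
#' @param occlusion list with `rate` (fraction of occluded frames) and
#'   `mean_duration_s` for rendered dropouts.
#' @param bad_cameras named list mapping camera name to
#'   `list(sigma_px = extra noise s.d., bias_px = c(dx, dy))`.
#' @param seed integer RNG seed for rendering noise and dropouts.
#' @return an object of class `synthetic_task_config`.
#' @export
synthetic_task_config <- function(task = c("static", "piano", "flexion",
                                           "extension", "ball"),
                                  n_reps = 10, fs = 30, duration_s = NULL,
                                  amplitudes = list(),
                                  noise_px = 0,
                                  occlusion = list(rate = 0, mean_duration_s = 0.2),
                                  bad_cameras = list(),
                                  seed = 0L) {
  task <- match.arg(task)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (fs <= 0) stop("fs must be positive")
  period <- 2
  if (is.null(duration_s))
    duration_s <- if (task == "static") 10 else n_reps * period
  if (duration_s <= 0) stop("duration_s must be positive")
  amp <- utils::modifyList(list(base = 80, middle = 100, distal = 70), amplitudes)
  if (noise_px < 0 || occlusion$rate < 0) stop("noise terms must be >= 0")
  structure(list(task = task, n_reps = n_reps, fs = fs,
                 duration_s = duration_s, amplitudes = amp,
                 noise_px = noise_px, occlusion = occlusion,
                 bad_cameras = bad_cameras, seed = as.integer(seed)),
            class = "synthetic_task_config")
}

# Raised-cosine pulse: 0 -> A -> 0 over [t_on, t_on + dur], C1-smooth.
raised_cosine <- function(t, t_on, dur, A) {
  inside <- t >= t_on & t <= t_on + dur
  out <- numeric(length(t))
  out[inside] <- A / 2 * (1 - cos(2 * pi * (t[inside] - t_on) / dur))
  out
}

#' Generate ground-truth motion for a synthetic task
#'
#' @param cfg a [synthetic_task_config()].
#' @param skeleton hand skeleton (default template right hand).
#' @return list with `poses` (T x 26), `track` (ground-truth [track3d()],
#'   all visible), and `angles` (ground-truth [joint_angle_series()] of the
#'   15 flexion DOFs). Deterministic: the motion itself uses no randomness.
#' @export
generate_motion <- function(cfg, skeleton = build_default_skeleton()) {
  TT <- max(2L, round(cfg$duration_s * cfg$fs))
  t <- (seq_len(TT) - 1) / cfg$fs
  poses <- matrix(0, TT, 26, dimnames = list(NULL, skeleton$dof_names))
  amp <- cfg$amplitudes
  period <- cfg$duration_s / cfg$n_reps
  dof0 <- function(d) 6L + 4L * (d - 1L)
  if (cfg$task == "static") {
    # palm down, fingers extended, no movement
  } else if (cfg$task == "piano") {
    # sequential non-overlapping per-finger pulses, pinky to thumb
    slot <- period / 5
    for (r in seq_len(cfg$n_reps) - 1) {
      for (k in 1:5) {
        d <- 6 - k  # digit 5 first, thumb last
        t_on <- r * period + (k - 1) * slot
        poses[, dof0(d) + 1] <- poses[, dof0(d) + 1] +
          raised_cosine(t, t_on, slot, min(amp$base, 60))
        poses[, dof0(d) + 3] <- poses[, dof0(d) + 3] +
          raised_cosine(t, t_on, slot, 40)
        poses[, dof0(d) + 4] <- poses[, dof0(d) + 4] +
          raised_cosine(t, t_on, slot, 25)
      }
    }
  } else if (cfg$task == "flexion") {
    for (r in seq_len(cfg$n_reps) - 1) {
      for (d in 1:5) {
        poses[, dof0(d) + 1] <- poses[, dof0(d) + 1] +
          raised_cosine(t, r * period, period, amp$base)
        poses[, dof0(d) + 3] <- poses[, dof0(d) + 3] +
          raised_cosine(t, r * period, period, amp$middle)
        poses[, dof0(d) + 4] <- poses[, dof0(d) + 4] +
          raised_cosine(t, r * period, period, amp$distal)
      }
    }
  } else if (cfg$task == "extension") {
    # relax (+15 deg) in the first half of each repetition, then
    # hyperextend (-20 deg base, limited to -10 deg middle/distal)
    for (r in seq_len(cfg$n_reps) - 1) {
      for (d in 1:5) {
        poses[, dof0(d) + 1] <- poses[, dof0(d) + 1] +
          raised_cosine(t, r * period, period / 2, 15) +
          raised_cosine(t, r * period + period / 2, period / 2, -20)
        for (off in c(3, 4))
          poses[, dof0(d) + off] <- poses[, dof0(d) + off] +
            raised_cosine(t, r * period, period / 2, 15) +
            raised_cosine(t, r * period + period / 2, period / 2, -10)
      }
    }
  } else if (cfg$task == "ball") {
    # grasp posture reached smoothly then held; whole hand translating
    # sinusoidally between two positions, with a small rotation
    grasp <- list(base = 45, middle = 60, distal = 30)
    ramp <- pmin(t / (period / 2), 1)
    ramp <- (1 - cos(pi * ramp)) / 2
    for (d in 1:5) {
      poses[, dof0(d) + 1] <- grasp$base * ramp
      poses[, dof0(d) + 3] <- grasp$middle * ramp
      poses[, dof0(d) + 4] <- grasp$distal * ramp
    }
    poses[, 1] <- 60 * (1 - cos(2 * pi * t / period))  # x shuttle, 120 mm
    poses[, 6] <- 8 * sin(2 * pi * t / period)          # small yaw
  }
  # clamp pulse overlap at repetition boundaries into the joint limits
  poses <- t(apply(poses, 1, clamp_pose, skeleton = skeleton))
  track <- fk_track(skeleton, poses, fs = cfg$fs)
  ang <- poses[, skeleton$joints$flex_dof, drop = FALSE]
  angles <- joint_angle_series(ang, joint_names = skeleton$joints$name,
                               fs = cfg$fs)
  list(poses = poses, track = track, angles = angles)
}

#' Build a virtual camera rig around the hand workspace
#'
#' Cameras are placed on an arc of radius `radius_mm` around the workspace
#' origin and oriented at it, at alternating elevations; when
#' `include_below` is TRUE the last camera views the hand from below.
#'
#' @param n_cameras number of cameras (2 to 8).
#' @param radius_mm distance from the origin (default 600).
#' @param image_size pixel dimensions (default 1280 x 720).
#' @param fov_deg horizontal field of view (default 70, webcam-like).
#' @param frame_rate Hz (default 30).
#' @param include_below place one camera below the hand plane.
#' @return a [camera_rig()] with cameras named `cam1`, `cam2`, ...
#' @export
make_rig <- function(n_cameras = 4, radius_mm = 600,
                     image_size = c(1280, 720), fov_deg = 70,
                     frame_rate = 30, include_below = TRUE) {
  if (n_cameras < 2) stop("need at least 2 cameras")
  if (n_cameras > 8) stop("at most 8 cameras supported")
  fx <- (image_size[1] / 2) / tan(fov_deg / 2 * DEG2RAD)
  pp <- (image_size - 1) / 2
  az <- seq(0, 300, length.out = n_cameras) * DEG2RAD
  elev <- rep(c(40, 25), length.out = n_cameras)
  if (include_below) elev[n_cameras] <- -35
  elev <- elev * DEG2RAD
  cams <- lapply(seq_len(n_cameras), function(i) {
    pos <- radius_mm * c(cos(elev[i]) * cos(az[i]),
                         cos(elev[i]) * sin(az[i]),
                         sin(elev[i]))
    z <- -pos / sqrt(sum(pos^2))           # optical axis toward the origin
    up <- c(0, 0, 1)
    if (abs(sum(z * up)) > 0.99) up <- c(1, 0, 0)
    x <- vcross(matrix(z, 1), matrix(up, 1))[1, ]
    x <- x / sqrt(sum(x^2))
    y <- vcross(matrix(z, 1), matrix(x, 1))[1, ]
    R <- rbind(x, y, z)
    dimnames(R) <- NULL
    camera_model(name = paste0("cam", i), image_size = image_size,
                 focal = c(fx, fx), principal_point = pp,
                 rotation = R, translation = as.numeric(-R %*% pos))
  })
  camera_rig(cams, frame_rate = frame_rate)
}

# Occluded-frame mask as alternating visible/occluded runs with geometric
# durations; long-run occluded fraction ~= rate.
dropout_mask <- function(TT, rate, mean_dur_frames) {
  if (rate <= 0 || mean_dur_frames <= 0) return(logical(TT))
  rate <- min(rate, 0.95)
  mean_occ <- max(1, mean_dur_frames)
  mean_vis <- mean_occ * (1 - rate) / rate
  occluded <- logical(TT)
  i <- 1
  state_occ <- stats::runif(1) < rate
  while (i <= TT) {
    len <- 1 + stats::rgeom(1, 1 / (if (state_occ) mean_occ else max(mean_vis, 1)))
    j <- min(TT, i + len - 1)
    if (state_occ) occluded[i:j] <- TRUE
    i <- j + 1
    state_occ <- !state_occ
  }
  occluded
}

#' Render a 3D track into per-camera 2D tracks
#'
#' Projects every visible landmark into every rig camera, adds isotropic
#' Gaussian pixel noise (`cfg$noise_px`, plus any per-camera extra noise and
#' bias from `cfg$bad_cameras`), and applies seeded contiguous occlusion
#' dropouts (`cfg$occlusion`). Landmarks behind a camera are excluded with
#' confidence 0 (with a warning). For the ball task, palm-side landmarks in
#' the below-hand camera receive three-fold dropout, emulating the ball
#' hiding the palm.
#'
#' @param track ground-truth [track3d()].
#' @param rig a [camera_rig()].
#' @param cfg a [synthetic_task_config()].
#' @return list of [track2d()], one per camera. Reproducible given
#'   `cfg$seed`.
#' @export
render_views <- function(track, rig, cfg) {
  set.seed(cfg$seed)
  TT <- n_frames(track); L <- length(track$landmark_names)
  palm_side <- track$landmark_names %in%
    c("WRIST", "THUMB_CMC", "INDEX_FINGER_MCP", "MIDDLE_FINGER_MCP",
      "RING_FINGER_MCP", "PINKY_MCP")
  below <- which.min(vapply(rig$cameras, function(cam)
    (-solve(cam$rotation) %*% cam$translation)[3], numeric(1)))
  out <- vector("list", length(rig$cameras))
  behind_any <- FALSE
  for (c in seq_along(rig$cameras)) {
    cam <- rig$cameras[[c]]
    bad <- cfg$bad_cameras[[cam$name]]
    sigma <- cfg$noise_px + if (!is.null(bad$sigma_px)) bad$sigma_px else 0
    bias <- if (!is.null(bad$bias_px)) bad$bias_px else c(0, 0)
    data <- array(NaN, c(TT, L, 2))
    conf <- matrix(0, TT, L)
    pts <- matrix(track$data, ncol = 3)
    px <- project_points(pts, cam)
    if (any(!is.finite(px[as.vector(track$visible), 1]))) behind_any <- TRUE
    for (l in seq_len(L)) {
      rows <- (l - 1) * TT + seq_len(TT)
      u <- px[rows, 1]; v <- px[rows, 2]
      ok <- track$visible[, l] & is.finite(u)
      if (sigma > 0) {
        u <- u + stats::rnorm(TT, 0, sigma)
        v <- v + stats::rnorm(TT, 0, sigma)
      }
      u <- u + bias[1]; v <- v + bias[2]
      rate <- cfg$occlusion$rate
      if (cfg$task == "ball" && c == below && palm_side[l])
        rate <- min(0.95, max(rate, 0.05) * 3)
      drop <- dropout_mask(TT, rate, cfg$occlusion$mean_duration_s * track$fs)
      ok <- ok & !drop
      data[ok, l, 1] <- u[ok]
      data[ok, l, 2] <- v[ok]
      conf[ok, l] <- 0.75 + 0.25 * stats::runif(sum(ok))
    }
    out[[c]] <- track2d(cam$name, data, conf,
                        landmark_names = track$landmark_names,
                        fs = track$fs, t0 = track$t0)
  }
  if (behind_any)
    warning("some landmarks fell behind a camera and were dropped (confidence 0)")
  out
}

#' Apply marker-dropout occlusion to a reference 3D track
#'
#' Emulates occlusion patterns of optoelectronic recordings: seeded
#' contiguous invisible runs, with a configurable elevated rate on the
#' wrist/palm landmarks (where heavy occlusion concentrates in practice).
#'
#' @param track a [track3d()].
#' @param pattern list with `rate` (target occluded fraction), `duration_s`
#'   (mean run duration) and `wrist_bias` (rate multiplier for wrist/palm
#'   landmarks, default 1).
#' @param seed RNG seed.
#' @return the occluded [track3d()] (occluded samples become NaN).
#' @export
simulate_reference_occlusion <- function(track,
                                         pattern = list(rate = 0.1,
                                                        duration_s = 0.3,
                                                        wrist_bias = 1),
                                         seed = 0L) {
  pattern <- utils::modifyList(list(rate = 0.1, duration_s = 0.3, wrist_bias = 1),
                               pattern)
  if (pattern$rate <= 0) return(track)
  set.seed(seed)
  TT <- n_frames(track)
  wristy <- track$landmark_names %in%
    c("WRIST", "THUMB_CMC", "INDEX_FINGER_MCP", "MIDDLE_FINGER_MCP",
      "RING_FINGER_MCP", "PINKY_MCP")
  visible <- track$visible
  for (l in seq_along(track$landmark_names)) {
    r <- pattern$rate * if (wristy[l]) pattern$wrist_bias else 1
    drop <- dropout_mask(TT, r, pattern$duration_s * track$fs)
    visible[drop, l] <- FALSE
  }
  track3d(track$data, visible = visible,
          landmark_names = track$landmark_names,
          fs = track$fs, t0 = track$t0, interpolated = track$interpolated)
}

#' Simulate a complete synthetic trial
#'
#' Generates ground-truth motion, renders it into the rig's cameras, and
#' produces a high-rate reference track (default 100 Hz) of the same
#' motion, optionally with reference marker dropout.
#'
#' @param cfg a [synthetic_task_config()].
#' @param rig a [camera_rig()] (default [make_rig()] with 4 cameras).
#' @param skeleton hand skeleton.
#' @param ref_fs reference-track sampling rate in Hz (default 100).
#' @param ref_occlusion optional occlusion `pattern` for
#'   [simulate_reference_occlusion()].
#' @return list with `cfg`, `rig`, `skeleton`, `truth` (the
#'   [generate_motion()] result at `cfg$fs`), `views` (list of
#'   [track2d()]), and `reference` (the [track3d()] at `ref_fs`).
#' @export
simulate_trial <- function(cfg, rig = make_rig(4), skeleton = build_default_skeleton(),
                           ref_fs = 100, ref_occlusion = NULL) {
  truth <- generate_motion(cfg, skeleton)
  views <- render_views(truth$track, rig, cfg)
  ref_cfg <- cfg
  ref_cfg$fs <- ref_fs
  ref <- generate_motion(ref_cfg, skeleton)$track
  if (!is.null(ref_occlusion))
    ref <- simulate_reference_occlusion(ref, ref_occlusion, seed = cfg$seed + 1L)
  list(cfg = cfg, rig = rig, skeleton = skeleton,
       truth = truth, views = views, reference = ref)
}
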