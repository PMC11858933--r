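# Containers for landmark trajectories: per-camera 2D tracks, world 3D
# tracks, and joint-angle time series.

#' The 21 hand landmark names (MediaPipe convention)
#'
#' @return character(21) in canonical order (WRIST first, PINKY_TIP last).
#' @export
hand_landmarks <- function() {
  c("WRIST",
    "THUMB_CMC", "THUMB_MCP", "THUMB_IP", "THUMB_TIP",
    "INDEX_FINGER_MCP", "INDEX_FINGER_PIP", "INDEX_FINGER_DIP", "INDEX_FINGER_TIP",
    "MIDDLE_FINGER_MCP", "MIDDLE_FINGER_PIP", "MIDDLE_FINGER_DIP", "MIDDLE_FINGER_TIP",
    "RING_FINGER_MCP", "RING_FINGER_PIP", "RING_FINGER_DIP", "RING_FINGER_TIP",
    "PINKY_MCP", "PINKY_PIP", "PINKY_DIP", "PINKY_TIP")
}

#' Construct a 2D landmark track for one camera
#'
#' @param camera_name camera the track was observed by.
#' @param data T x L x 2 array of pixel coordinates (NaN where unobserved).
#' @param confidence T x L matrix of detector confidences in [0, 1].
#' @param landmark_names character(L); defaults to [hand_landmarks()].
#' @param fs sampling rate in Hz.
#' @param t0 time of the first frame in seconds.
#' @return an object of class `track2d`.
#' @export
track2d <- function(camera_name, data, confidence,
                    landmark_names = hand_landmarks(), fs = 30, t0 = 0) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == 2)
  if (!all(dim(confidence) == dim(data)[1:2]))
    stop("confidence shape does not match data")
  if (dim(data)[2] != length(landmark_names))
    stop("landmark_names length does not match data")
  if (fs <= 0) stop("fs must be positive")
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop("confidence must lie in [0, 1]")
  # NaN coordinates <=> confidence 0
  nan <- is.na(data[, , 1]) | is.na(data[, , 2])
  confidence[nan] <- 0
  data[, , 1][confidence == 0] <- NaN
  data[, , 2][confidence == 0] <- NaN
  structure(list(camera_name = camera_name, data = data,
                 confidence = confidence, landmark_names = landmark_names,
                 fs = fs, t0 = t0),
            class = "track2d")
}

#' @export
print.track2d <- function(x, ...) {
  cat(sprintf("<track2d '%s'> %d frames x %d landmarks @ %g Hz, mean confidence %.2f\n",
              x$camera_name, dim(x$data)[1], dim(x$data)[2], x$fs,
              mean(x$confidence)))
  invisible(x)
}

#' Construct a 3D landmark track
#'
#' @param data T x L x 3 array of world coordinates in mm (NaN where the
#'   landmark is not visible).
#' @param visible T x L logical matrix; invisible entries carry NaN.
#' @param landmark_names character(L).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first frame in seconds.
#' @param interpolated optional T x L logical provenance mask marking
#'   gap-filled samples (visible but not directly observed).
#' @return an object of class `track3d`.
#' @export
track3d <- function(data, visible = NULL, landmark_names = hand_landmarks(),
                    fs = 30, t0 = 0, interpolated = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == 3)
  TT <- dim(data)[1]; L <- dim(data)[2]
  if (L != length(landmark_names))
    stop("landmark_names length does not match data")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(visible))
    visible <- !(is.na(data[, , 1]) | is.na(data[, , 2]) | is.na(data[, , 3]))
  visible <- matrix(as.logical(visible), TT, L)
  for (k in 1:3) data[, , k][!visible] <- NaN
  if (is.null(interpolated)) interpolated <- matrix(FALSE, TT, L)
  structure(list(data = data, visible = visible,
                 landmark_names = landmark_names, fs = fs, t0 = t0,
                 interpolated = interpolated),
            class = "track3d")
}

#' @export
print.track3d <- function(x, ...) {
  cat(sprintf("<track3d> %d frames x %d landmarks @ %g Hz, %.1f%% visible\n",
              dim(x$data)[1], dim(x$data)[2], x$fs, 100 * mean(x$visible)))
  invisible(x)
}

n_frames <- function(track) dim(track$data)[1]

track_times <- function(track) track$t0 + (seq_len(n_frames(track)) - 1) / track$fs

# Coordinates of one frame as an L x 3 matrix
frame_points <- function(track, i) {
  matrix(track$data[i, , ], ncol = 3)
}

#' Construct a joint-angle time series
#'
#' @param angles T x J matrix of joint angles in degrees (NaN where invalid).
#' @param joint_names character(J); defaults to [hand_joint_names()].
#' @param valid T x J logical validity mask.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first frame in seconds.
#' @return an object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(angles, joint_names = hand_joint_names(),
                               valid = NULL, fs = 30, t0 = 0) {
  angles <- as.matrix(angles)
  if (ncol(angles) != length(joint_names))
    stop("joint_names length does not match angles")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(valid)) valid <- !is.na(angles)
  valid <- matrix(as.logical(valid), nrow(angles), ncol(angles))
  angles[!valid] <- NaN
  colnames(angles) <- joint_names
  structure(list(angles = angles, joint_names = joint_names, valid = valid,
                 fs = fs, t0 = t0),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d frames x %d joints @ %g Hz, %.1f%% valid\n",
              nrow(x$angles), ncol(x$angles), x$fs, 100 * mean(x$valid)))
  invisible(x)
}

#' Plot a joint-angle time series
#'
#' One line per joint, degrees against time.
#'
#' @param x a [joint_angle_series()].
#' @param joints optional character vector of joint names to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.joint_angle_series <- function(x, joints = NULL, ...) {
  idx <- if (is.null(joints)) seq_along(x$joint_names)
         else match(joints, x$joint_names)
  if (anyNA(idx)) stop("unknown joint name")
  t <- x$t0 + (seq_len(nrow(x$angles)) - 1) / x$fs
  graphics::matplot(t, x$angles[, idx, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (s)", ylab = "angle (deg)", ...)
  graphics::legend("topright", legend = x$joint_names[idx], lty = 1,
                   col = seq_along(idx), cex = 0.7, bty = "n")
  invisible(x)
}
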