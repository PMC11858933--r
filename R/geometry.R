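# Pinhole camera models and calibration-rig I/O.
#
# Conventions: world units are millimetres; pixel origin is the top-left
# corner with x right and y down, and pixel centers at integer coordinates.
# rotation/translation map world -> camera: X_cam = R X_world + t.

#' Construct a calibrated pinhole camera
#'
#' @param name unique camera identifier.
#' @param image_size integer(2), image width and height in pixels.
#' @param focal numeric(2), focal lengths (fx, fy) in pixels.
#' @param principal_point numeric(2), principal point (cx, cy) in pixels.
#' @param distortion numeric(5), radial/tangential coefficients
#'   (k1, k2, p1, p2, k3); defaults to zero.
#' @param rotation 3x3 orthonormal world-to-camera rotation matrix.
#' @param translation numeric(3), world-to-camera translation in mm.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(name, image_size, focal, principal_point,
                         distortion = numeric(5),
                         rotation = diag(3), translation = c(0, 0, 0)) {
  cam <- structure(
    list(name = as.character(name),
         image_size = as.numeric(image_size),
         focal = as.numeric(focal),
         principal_point = as.numeric(principal_point),
         distortion = as.numeric(distortion),
         rotation = rotation,
         translation = as.numeric(translation)),
    class = "camera_model")
  validate_camera_model(cam)
}

validate_camera_model <- function(cam, tol = 1e-9) {
  with(cam, {
    if (length(name) != 1L || !nzchar(name))
      stop("camera needs a non-empty name")
    if (length(image_size) != 2 || any(image_size <= 0))
      stop(sprintf("camera '%s': image_size must be two positive numbers", name))
    if (length(focal) != 2 || any(focal <= 0))
      stop(sprintf("camera '%s': focal lengths must be positive", name))
    if (length(principal_point) != 2)
      stop(sprintf("camera '%s': principal_point must have length 2", name))
    if (length(distortion) != 5)
      stop(sprintf("camera '%s': distortion must have 5 coefficients", name))
    if (!is_rotation_matrix(rotation, tol))
      stop(sprintf("camera '%s': rotation is not a proper rotation matrix", name))
    if (length(translation) != 3)
      stop(sprintf("camera '%s': translation must have length 3", name))
  })
  cam
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model '%s'>  %gx%g px, f = (%.6g, %.6g) px\n",
              x$name, x$image_size[1], x$image_size[2], x$focal[1], x$focal[2]))
  invisible(x)
}

#' Construct a multi-camera rig
#'
#' @param cameras list of [camera_model()] objects with unique names.
#' @param frame_rate acquisition rate in Hz.
#' @return an object of class `camera_rig`. World units are always mm.
#' @export
camera_rig <- function(cameras, frame_rate = 30) {
  if (length(cameras) < 1) stop("a rig needs at least one camera")
  nm <- vapply(cameras, function(c) c$name, character(1))
  if (anyDuplicated(nm)) stop("camera names must be unique")
  structure(list(cameras = stats::setNames(cameras, nm),
                 world_units = "mm", frame_rate = frame_rate),
            class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf("<camera_rig> %d cameras @ %g Hz: %s\n",
              length(x$cameras), x$frame_rate,
              paste(names(x$cameras), collapse = ", ")))
  invisible(x)
}

camera_names <- function(rig) names(rig$cameras)

#' Project a 3D world point into a camera
#'
#' Applies the rigid world-to-camera transform, perspective division,
#' radial/tangential distortion and the focal/principal-point scaling.
#'
#' @param point numeric(3), world coordinates in mm.
#' @param cam a [camera_model()].
#' @return numeric(2) pixel coordinates.
#' @export
project <- function(point, cam) {
  stopifnot(length(point) == 3)
  Xc <- as.numeric(cam$rotation %*% point + cam$translation)
  if (Xc[3] <= 0)
    stop(sprintf("point is behind camera '%s' (depth %.3f mm)", cam$name, Xc[3]))
  drop(project_points(matrix(point, 1, 3), cam))
}

# Vectorized projection of an n x 3 matrix; points behind the camera give NaN.
project_points <- function(points, cam) {
  Xc <- points %*% t(cam$rotation)
  Xc <- sweep(Xc, 2, cam$translation, `+`)
  z <- Xc[, 3]
  bad <- !(z > 0) | !is.finite(z)
  z[bad] <- NA_real_
  x <- Xc[, 1] / z
  y <- Xc[, 2] / z
  d <- cam$distortion
  r2 <- x^2 + y^2
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  xd <- x * radial + 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
  yd <- y * radial + d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
  out <- cbind(cam$focal[1] * xd + cam$principal_point[1],
               cam$focal[2] * yd + cam$principal_point[2])
  out[bad, ] <- NaN
  out
}

# Invert the distortion model: pixel coords -> undistorted normalized coords.
# Fixed-point iteration, adequate for the mild distortion of webcam lenses.
undistort_points <- function(px, cam, iterations = 25) {
  xd <- (px[, 1] - cam$principal_point[1]) / cam$focal[1]
  yd <- (px[, 2] - cam$principal_point[2]) / cam$focal[2]
  d <- cam$distortion
  if (all(d == 0)) return(cbind(xd, yd))
  x <- xd; y <- yd
  for (i in seq_len(iterations)) {
    r2 <- x^2 + y^2
    radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
    dx <- 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
    dy <- d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
    x <- (xd - dx) / radial
    y <- (yd - dy) / radial
  }
  cbind(x, y)
}

#' Read a camera rig from a calibration file
#'
#' JSON schema: a top-level `cameras` array (or a map of per-camera
#' objects) with fields `name`, `image_size`, either `matrix` (3x3 row-major
#' K) or `focal` + `principal_point`, `distortion` (5 values, optional),
#' either `rotation` (3x3 row-major) or `rodrigues` (3-vector, radians),
#' `translation`, and optional `units` ("mm", the default, or "m").
#' An optional top-level `frame_rate` gives the acquisition rate.
#'
#' @param path path to the JSON calibration file.
#' @return a validated [camera_rig()], with all lengths in mm.
#' @export
load_rig <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cams_raw <- if (!is.null(raw$cameras)) raw$cameras else raw
  if (!is.list(cams_raw) || length(cams_raw) == 0)
    stop("calibration file has no cameras")
  cams <- lapply(seq_along(cams_raw), function(i) {
    c0 <- cams_raw[[i]]
    nm <- c0$name
    if (is.null(nm)) nm <- names(cams_raw)[i]
    if (is.null(nm) || !nzchar(nm))
      stop(sprintf("camera #%d: missing name", i))
    need <- function(field) {
      if (is.null(c0[[field]]))
        stop(sprintf("camera '%s': missing field '%s'", nm, field))
      c0[[field]]
    }
    scale <- 1
    if (!is.null(c0$units)) {
      if (c0$units == "m") scale <- 1000
      else if (c0$units != "mm")
        stop(sprintf("camera '%s': unknown units '%s'", nm, c0$units))
    }
    if (!is.null(c0$matrix)) {
      K <- matrix(as.numeric(unlist(c0$matrix)), 3, 3, byrow = TRUE)
      focal <- c(K[1, 1], K[2, 2]); pp <- c(K[1, 3], K[2, 3])
    } else {
      focal <- as.numeric(need("focal"))
      pp <- as.numeric(need("principal_point"))
    }
    if (!is.null(c0$rotation)) {
      R <- matrix(as.numeric(unlist(c0$rotation)), 3, 3, byrow = TRUE)
      if (!is_rotation_matrix(R, tol = 1e-6))
        stop(sprintf("camera '%s': rotation is not orthonormal with det +1", nm))
    } else if (!is.null(c0$rodrigues)) {
      R <- rodrigues_to_matrix(as.numeric(c0$rodrigues))
    } else stop(sprintf("camera '%s': missing field 'rotation' (or 'rodrigues')", nm))
    camera_model(name = nm,
                 image_size = as.numeric(need("image_size")),
                 focal = focal, principal_point = pp,
                 distortion = if (is.null(c0$distortion)) numeric(5)
                              else as.numeric(c0$distortion),
                 rotation = R,
                 translation = as.numeric(need("translation")) * scale)
  })
  nm <- vapply(cams, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate camera name: ", nm[duplicated(nm)][1])
  fr <- if (!is.null(raw$frame_rate)) raw$frame_rate else 30
  camera_rig(cams, frame_rate = fr)
}

#' Write a camera rig to a JSON calibration file
#'
#' Numeric fields are written at full precision so that
#' `load_rig(save_rig(rig, path))` round-trips exactly.
#'
#' @param rig a [camera_rig()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_rig <- function(rig, path) {
  cams <- lapply(rig$cameras, function(cam) {
    list(name = cam$name,
         image_size = cam$image_size,
         focal = cam$focal,
         principal_point = cam$principal_point,
         distortion = cam$distortion,
         rotation = as.numeric(t(cam$rotation)),  # row-major
         translation = cam$translation,
         units = "mm")
  })
  jsonlite::write_json(list(frame_rate = rig$frame_rate, cameras = unname(cams)),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
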