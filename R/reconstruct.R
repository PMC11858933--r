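# Multi-camera triangulation and camera-subset selection.
#
# A landmark observed in >= 2 calibrated cameras is reconstructed by linear
# DLT triangulation on undistorted normalized coordinates. A trial's camera
# subset is chosen from two error criteria: the per-camera reprojection RMSE
# (converted to mm at the hand's distance) and the anatomical error (RMS over
# finger segments of the temporal standard deviation of segment length),
# with thresholds of 10 mm and 5 mm respectively.

#' Triangulate one 3D point from multiple camera observations
#'
#' Linear DLT least squares: the homogeneous constraints from each camera's
#' undistorted normalized coordinates are stacked and solved by SVD.
#'
#' @param observations list of `list(cam = camera_model, px = c(u, v))`
#'   entries, one per camera (>= 2 distinct cameras).
#' @return numeric(3) world point in mm.
#' @export
triangulate_point <- function(observations) {
  if (length(observations) < 2)
    stop("insufficient views: need at least 2 observations")
  A <- matrix(0, 2 * length(observations), 4)
  for (i in seq_along(observations)) {
    ob <- observations[[i]]
    xy <- undistort_points(matrix(ob$px, 1, 2), ob$cam)
    P <- cbind(ob$cam$rotation, ob$cam$translation)
    A[2 * i - 1, ] <- xy[1] * P[3, ] - P[1, ]
    A[2 * i, ]     <- xy[2] * P[3, ] - P[2, ]
  }
  # inhomogeneous DLT: fix the homogeneous scale w = 1 and solve the
  # stacked constraints A [X; 1] = 0 for X in least squares. (The |v| = 1
  # homogeneous form is scale-biased for mm-unit scenes: it discounts the
  # algebraic error of distant candidates by 1/|X|.)
  s <- svd(A[, 1:3, drop = FALSE])
  if (s$d[1] / max(s$d[3], .Machine$double.xmin) > 1e12)
    stop("degenerate configuration: camera rays are (near-)parallel")
  as.numeric(s$v %*% ((t(s$u) %*% (-A[, 4])) / s$d))
}

#' Triangulate multi-camera 2D tracks into a 3D track
#'
#' Per frame and landmark, the cameras of `subset` whose confidence is at
#' least `min_confidence` are used; a landmark with fewer than two usable
#' views is marked invisible for that frame.
#'
#' @param tracks list of [track2d()] objects (one per camera) sharing
#'   sampling rate, start time and landmark names.
#' @param rig the [camera_rig()].
#' @param subset character vector of camera names to use; default all
#'   cameras present in `tracks`.
#' @param min_confidence minimum 2D confidence to use an observation
#'   (default 0.5).
#' @return a [track3d()] at the tracks' rate.
#' @export
triangulate_tracks <- function(tracks, rig, subset = NULL, min_confidence = 0.5) {
  tnames <- vapply(tracks, function(t) t$camera_name, character(1))
  if (is.null(subset)) subset <- tnames
  missing_rig <- setdiff(subset, camera_names(rig))
  if (length(missing_rig))
    stop("track mismatch: cameras not in rig: ", paste(missing_rig, collapse = ", "))
  missing_trk <- setdiff(subset, tnames)
  if (length(missing_trk))
    stop("track mismatch: no 2D track for camera(s): ",
         paste(missing_trk, collapse = ", "))
  use <- tracks[match(subset, tnames)]
  ref <- use[[1]]
  for (t in use[-1]) {
    if (!isTRUE(all.equal(t$fs, ref$fs)) || !isTRUE(all.equal(t$t0, ref$t0)) ||
        n_frames_2d(t) != n_frames_2d(ref) ||
        !identical(t$landmark_names, ref$landmark_names))
      stop("track mismatch: tracks differ in frames, rate, t0 or landmark names")
  }
  cams <- rig$cameras[subset]
  TT <- n_frames_2d(ref); L <- length(ref$landmark_names)
  data <- array(NaN, c(TT, L, 3))
  for (f in seq_len(TT)) {
    for (l in seq_len(L)) {
      obs <- list()
      for (c in seq_along(use)) {
        if (use[[c]]$confidence[f, l] >= min_confidence &&
            is.finite(use[[c]]$data[f, l, 1])) {
          obs[[length(obs) + 1]] <- list(cam = cams[[c]],
                                         px = use[[c]]$data[f, l, ])
        }
      }
      if (length(obs) >= 2) {
        p <- tryCatch(triangulate_point(obs), error = function(e) NULL)
        if (!is.null(p)) data[f, l, ] <- p
      }
    }
  }
  track3d(data, landmark_names = ref$landmark_names, fs = ref$fs, t0 = ref$t0)
}

n_frames_2d <- function(track) dim(track$data)[1]

#' Per-camera reprojection RMSE of a triangulated track
#'
#' For each camera of the subset: the RMSE, over all (frame, landmark) pairs
#' that are visible in the 3D track and observed in that camera, of the
#' distance between the observed 2D landmark and the reprojected 3D
#' estimate. The mm conversion multiplies the pixel error by
#' `median(depth) / mean(focal)` for that camera, mapping image error to
#' metric error at the hand's distance.
#'
#' @param track3d the triangulated [track3d()].
#' @param tracks list of [track2d()] used for the triangulation.
#' @param rig the [camera_rig()].
#' @param subset camera names to evaluate.
#' @param min_confidence observations below this confidence are ignored.
#' @return list with `px` and `mm` (named per-camera RMSEs) and `pooled_mm`
#'   (RMSE pooled over all cameras' residuals, in mm).
#' @export
reprojection_rmse <- function(track3d, tracks, rig, subset = NULL,
                              min_confidence = 0.5) {
  tnames <- vapply(tracks, function(t) t$camera_name, character(1))
  if (is.null(subset)) subset <- tnames
  # flatten T x L x 3 to (T*L) x 3; column-major order matches as.vector(visible)
  pts <- matrix(track3d$data, ncol = 3)
  vis3 <- as.vector(track3d$visible)
  px_rmse <- mm_rmse <- stats::setNames(numeric(length(subset)), subset)
  pooled_sq <- 0; pooled_n <- 0
  for (cn in subset) {
    cam <- rig$cameras[[cn]]
    t2 <- tracks[[match(cn, tnames)]]
    obs <- matrix(t2$data, ncol = 2)
    conf <- as.vector(t2$confidence)
    ok <- vis3 & conf >= min_confidence & is.finite(obs[, 1])
    if (!any(ok))
      stop(sprintf("no support: camera '%s' shares no visible pairs with the 3D track", cn))
    proj <- project_points(pts[ok, , drop = FALSE], cam)
    err2 <- rowSums((proj - obs[ok, , drop = FALSE])^2)
    err2 <- err2[is.finite(err2)]
    px_rmse[cn] <- sqrt(mean(err2))
    # depth of the triangulated points in this camera's frame
    Xc <- pts[ok, , drop = FALSE] %*% t(cam$rotation)
    z_med <- stats::median(Xc[, 3] + cam$translation[3])
    scale_mm <- z_med / mean(cam$focal)
    mm_rmse[cn] <- px_rmse[cn] * scale_mm
    pooled_sq <- pooled_sq + sum(err2 * scale_mm^2)
    pooled_n <- pooled_n + length(err2)
  }
  list(px = px_rmse, mm = mm_rmse, pooled_mm = sqrt(pooled_sq / pooled_n))
}

#' Anatomical (segment-length consistency) error
#'
#' Per finger segment, the sample standard deviation (ddof = 1) of its
#' frame-wise length over frames where both endpoints are visible; the
#' result is the root mean square of those standard deviations over the 15
#' phalanx segments. Segments with fewer than 2 supported frames are
#' excluded (and reported in the `"excluded_segments"` attribute).
#'
#' @param track3d a [track3d()].
#' @param skeleton a hand skeleton.
#' @return scalar error in mm, with attribute `excluded_segments`.
#' @export
anatomical_error <- function(track3d, skeleton) {
  len <- segment_lengths(track3d, skeleton)
  phal <- skeleton$segments$type != "ray"
  len <- len[, phal, drop = FALSE]
  sds <- apply(len, 2, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x)
  })
  ok <- !is.na(sds)
  if (!any(ok)) stop("no support: no finger segment has >= 2 visible frames")
  out <- sqrt(mean(sds[ok]^2))
  attr(out, "excluded_segments") <- colnames(len)[!ok]
  out
}

#' Enumerate camera subsets
#'
#' All subsets of size `min_size` up to `n_cameras`, ordered by size
#' descending then lexicographically.
#'
#' @param n_cameras number of cameras (or a character vector of names).
#' @param min_size smallest subset size (default 2).
#' @return list of integer vectors (or character vectors if names given).
#' @export
enumerate_subsets <- function(n_cameras, min_size = 2) {
  names <- NULL
  if (is.character(n_cameras)) { names <- n_cameras; n_cameras <- length(names) }
  if (min_size < 2) stop("min_size must be >= 2")
  if (n_cameras < min_size)
    stop("n_cameras must be at least min_size")
  out <- list()
  for (k in seq(n_cameras, min_size)) {
    cmb <- utils::combn(n_cameras, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  if (!is.null(names)) out <- lapply(out, function(i) names[i])
  out
}

#' Select the optimal camera subset for a trial
#'
#' Scores every subset of >= 2 cameras (triangulation, per-camera
#' reprojection RMSE, anatomical error). A subset passes if its worst
#' per-camera reprojection RMSE (in mm) is at most `thresholds$reproj_mm`
#' and its anatomical error at most `thresholds$anat_mm`. Among passing
#' subsets the one of maximal cardinality is chosen (ties broken by lower
#' anatomical error, then lower pooled reprojection error, then enumeration
#' order). If no subset passes, the subset minimizing
#' `anatomical/anat_mm + pooled_reproj/reproj_mm` is returned as best
#' effort.
#'
#' @param tracks list of [track2d()] (>= 2 cameras).
#' @param rig the [camera_rig()].
#' @param skeleton hand skeleton (for the anatomical error).
#' @param thresholds list with `reproj_mm` (default 10) and `anat_mm`
#'   (default 5).
#' @param min_confidence minimum 2D confidence (default 0.5).
#' @return an object of class `selection_result`: list with `chosen` (the
#'   winning subset score), `all_scores`, and `reason` (one of `all_pass`,
#'   `fallback_smaller`, `none_pass_best_effort`).
#' @export
select_subset <- function(tracks, rig, skeleton,
                          thresholds = list(reproj_mm = 10, anat_mm = 5),
                          min_confidence = 0.5) {
  tnames <- vapply(tracks, function(t) t$camera_name, character(1))
  if (length(tnames) < 2) stop("need tracks from at least 2 cameras")
  subsets <- enumerate_subsets(sort(tnames), min_size = 2)
  scores <- list()
  failed <- character(0)
  for (sub in subsets) {
    sc <- tryCatch(
      score_subset(sub, tracks, rig, skeleton, thresholds, min_confidence),
      error = function(e) e)
    if (inherits(sc, "error")) {
      failed <- c(failed, paste0("{", paste(sub, collapse = ","), "}: ",
                                 conditionMessage(sc)))
      next
    }
    scores[[length(scores) + 1]] <- sc
  }
  if (length(failed))
    message("select_subset: excluded unscorable subset(s): ",
            paste(failed, collapse = "; "))
  if (!length(scores)) stop("no camera subset could be scored")
  pass <- vapply(scores, function(s) s$passes_reproj && s$passes_anat, logical(1))
  if (any(pass)) {
    cand <- which(pass)
    sizes <- vapply(scores[cand], function(s) length(s$subset), numeric(1))
    cand <- cand[sizes == max(sizes)]
    if (length(cand) > 1) {
      o <- order(vapply(scores[cand], `[[`, numeric(1), "anatomical_mm"),
                 vapply(scores[cand], `[[`, numeric(1), "reproj_pooled_mm"))
      cand <- cand[o]
    }
    chosen <- scores[[cand[1]]]
    reason <- if (length(chosen$subset) == length(tnames)) "all_pass"
              else "fallback_smaller"
  } else {
    obj <- vapply(scores, function(s)
      s$anatomical_mm / thresholds$anat_mm +
        s$reproj_pooled_mm / thresholds$reproj_mm, numeric(1))
    chosen <- scores[[which.min(obj)]]
    reason <- "none_pass_best_effort"
  }
  structure(list(chosen = chosen, all_scores = scores, reason = reason,
                 thresholds = thresholds),
            class = "selection_result")
}

score_subset <- function(subset, tracks, rig, skeleton, thresholds,
                         min_confidence) {
  t3 <- triangulate_tracks(tracks, rig, subset, min_confidence)
  rp <- reprojection_rmse(t3, tracks, rig, subset, min_confidence)
  an <- anatomical_error(t3, skeleton)
  structure(list(subset = subset,
                 reproj_rmse_px = rp$px,
                 reproj_rmse_mm = rp$mm,
                 reproj_pooled_mm = rp$pooled_mm,
                 anatomical_mm = as.numeric(an),
                 passes_reproj = max(rp$mm) <= thresholds$reproj_mm,
                 passes_anat = as.numeric(an) <= thresholds$anat_mm),
            class = "subset_score")
}

#' @export
print.subset_score <- function(x, ...) {
  cat(sprintf("<subset_score> {%s}: reproj %.2f mm (worst cam), anat %.2f mm [%s]\n",
              paste(x$subset, collapse = ","), max(x$reproj_rmse_mm),
              x$anatomical_mm,
              if (x$passes_reproj && x$passes_anat) "pass" else "fail"))
  invisible(x)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> chosen {%s} (%s)\n",
              paste(x$chosen$subset, collapse = ","), x$reason))
  for (s in x$all_scores) print(s)
  invisible(x)
}

#' @export
summary.selection_result <- function(object, ...) {
  df <- do.call(rbind, lapply(object$all_scores, function(s)
    data.frame(subset = paste(s$subset, collapse = ","),
               n_cameras = length(s$subset),
               worst_reproj_mm = max(s$reproj_rmse_mm),
               pooled_reproj_mm = s$reproj_pooled_mm,
               anatomical_mm = s$anatomical_mm,
               passes = s$passes_reproj && s$passes_anat)))
  df$chosen <- df$subset == paste(object$chosen$subset, collapse = ",")
  df
}
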