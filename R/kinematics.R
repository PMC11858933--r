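# Forward and inverse kinematics of the articulated hand.
#
# Pose vector q (length 26), all angles in degrees at the interface:
#   q[1:3]  global translation (mm)
#   q[4:6]  global orientation, XYZ Euler angles applied as Rz(rz) Ry(ry) Rx(rx)
#   then per digit d = 1..5: base flexion, base abduction, middle flexion,
#   distal flexion.

#' Default IK marker weights
#'
#' Weight 1 for the four landmarks of each finger chain (MCP, PIP, DIP, TIP)
#' and the three proximal thumb landmarks (CMC, MCP, IP); weight 0.1 for the
#' wrist and the thumb tip, which carry less anatomical reliability.
#'
#' @param skeleton a hand skeleton.
#' @return named numeric(21) of per-landmark weights.
#' @export
default_ik_weights <- function(skeleton = build_default_skeleton()) {
  w <- rep(1, 21)
  names(w) <- skeleton$landmark_names
  w[c("WRIST", "THUMB_TIP")] <- 0.1
  w
}

check_pose_limits <- function(skeleton, q, tol = 1e-9) {
  bad <- which(q < skeleton$limits_lower - tol | q > skeleton$limits_upper + tol)
  if (length(bad))
    stop("pose outside joint limits for DOF(s): ",
         paste(skeleton$dof_names[bad], collapse = ", "))
}

clamp_pose <- function(skeleton, q) {
  pmin(pmax(q, skeleton$limits_lower), skeleton$limits_upper)
}

# Global rotation Rz(rz) Ry(ry) Rx(rx), angles in degrees.
global_rotation <- function(q) {
  rx <- q[4] * DEG2RAD; ry <- q[5] * DEG2RAD; rz <- q[6] * DEG2RAD
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Extract (rx, ry, rz) in degrees such that global_rotation() reproduces R.
euler_from_matrix <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock: fold rz into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * RAD2DEG
}

#' Forward kinematics
#'
#' Computes the 21 landmark positions from a pose. Segments are rigid; each
#' digit applies base abduction about the palm normal, base flexion about the
#' axis perpendicular to the digit in the palm plane, then middle and distal
#' hinge flexions about that axis carried along the chain.
#'
#' @param skeleton a [build_default_skeleton()] skeleton.
#' @param pose numeric(26) pose vector (degrees / mm).
#' @param check enforce joint limits (default TRUE).
#' @return 21 x 3 matrix of landmark positions (mm), rows named.
#' @export
forward_kinematics <- function(skeleton, pose, check = TRUE) {
  fk_eval(skeleton, pose, check = check)$points
}

# FK workhorse: returns landmark points and, for the IK Jacobian, the world
# axis, center and affected landmarks of every angular DOF.
fk_eval <- function(skeleton, q, check = TRUE, with_axes = FALSE) {
  stopifnot(length(q) == 26)
  if (check) check_pose_limits(skeleton, q)
  t_g <- q[1:3]
  Rg <- global_rotation(q)
  chains <- digit_chains()
  n <- skeleton$normal
  pts <- matrix(0, 21, 3, dimnames = list(skeleton$landmark_names, NULL))
  axes <- if (with_axes) vector("list", 26) else NULL
  pts[1, ] <- t_g  # wrist at local origin
  for (d in 1:5) {
    u <- skeleton$digit_dirs[, d]
    a <- c(n[2] * u[3] - n[3] * u[2],
           n[3] * u[1] - n[1] * u[3],
           n[1] * u[2] - n[2] * u[1])          # cross(n, u), unit
    i0 <- 6L + 4L * (d - 1L)
    th1 <- q[i0 + 1] * DEG2RAD; phi <- q[i0 + 2] * DEG2RAD
    th2 <- q[i0 + 3] * DEG2RAD; th3 <- q[i0 + 4] * DEG2RAD
    L <- skeleton$phal_lengths[[d]]
    b <- skeleton$ray_lengths[d] * u
    Rab <- rotation_about(n, phi)
    C1 <- Rab %*% rotation_about(a, th1)
    p1 <- b                                    # digit base (on the rigid palm)
    p2 <- p1 + L[1] * (C1 %*% u)
    a2 <- C1 %*% a
    C2 <- rotation_about(a2, th2) %*% C1
    p3 <- p2 + L[2] * (C2 %*% u)
    a3 <- C2 %*% a
    C3 <- rotation_about(a3, th3) %*% C2
    p4 <- p3 + L[3] * (C3 %*% u)
    ch <- chains[[d]]
    pts[ch[1], ] <- Rg %*% p1 + t_g
    pts[ch[2], ] <- Rg %*% p2 + t_g
    pts[ch[3], ] <- Rg %*% p3 + t_g
    pts[ch[4], ] <- Rg %*% p4 + t_g
    if (with_axes) {
      axes[[i0 + 1]] <- list(axis = as.numeric(Rg %*% (Rab %*% a)),
                             center = pts[ch[1], ], landmarks = ch[2:4])
      axes[[i0 + 2]] <- list(axis = as.numeric(Rg %*% n),
                             center = pts[ch[1], ], landmarks = ch[2:4])
      axes[[i0 + 3]] <- list(axis = as.numeric(Rg %*% a2),
                             center = pts[ch[2], ], landmarks = ch[3:4])
      axes[[i0 + 4]] <- list(axis = as.numeric(Rg %*% a3),
                             center = pts[ch[3], ], landmarks = ch[4])
    }
  }
  list(points = pts, axes = axes, Rg = Rg, t = t_g)
}

# Weighted-residual IK Jacobian: rows = 3 per visible landmark (in `vis`
# order), columns = 26 DOFs, angular columns in degrees.
ik_jacobian <- function(skeleton, fk, vis, sw) {
  V <- length(vis)
  J <- matrix(0, 3 * V, 26)
  p <- fk$points[vis, , drop = FALSE]
  rel <- sweep(p, 2, fk$t)                    # p - t for the global rotation
  for (k in seq_len(V)) {
    rows <- (3 * k - 2):(3 * k)
    J[rows, 1:3] <- diag(3) * sw[k]
  }
  # global rotation columns
  gr <- attr(fk, "global_axes")
  for (j in 1:3) {
    ax <- gr[, j]
    cr <- cbind(ax[2] * rel[, 3] - ax[3] * rel[, 2],
                ax[3] * rel[, 1] - ax[1] * rel[, 3],
                ax[1] * rel[, 2] - ax[2] * rel[, 1]) * DEG2RAD
    for (k in seq_len(V)) J[(3 * k - 2):(3 * k), 3 + j] <- cr[k, ] * sw[k]
  }
  # hinge columns
  for (dof in 7:26) {
    info <- fk$axes[[dof]]
    hit <- match(info$landmarks, vis)
    hit <- hit[!is.na(hit)]
    if (!length(hit)) next
    ax <- info$axis
    for (k in hit) {
      r <- fk$points[vis[k], ] - info$center
      J[(3 * k - 2):(3 * k), dof] <-
        c(ax[2] * r[3] - ax[3] * r[2],
          ax[3] * r[1] - ax[1] * r[3],
          ax[1] * r[2] - ax[2] * r[1]) * DEG2RAD * sw[k]
    }
  }
  J
}

# World axes of the three global-orientation DOFs, as a 3 x 3 matrix of
# columns (d/drx, d/dry, d/drz).
global_rotation_axes <- function(q) {
  ry <- q[5] * DEG2RAD; rz <- q[6] * DEG2RAD
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  cbind(Rz %*% Ry %*% c(1, 0, 0), Rz %*% c(0, 1, 0), c(0, 0, 1))
}

#' Direct geometric joint angles
#'
#' For each joint, the angle between the proximal and distal bone direction
#' vectors (0 deg = straight chain), signed positive toward the palmar side
#' using the measured palm normal (cross product of the wrist-to-index-base
#' and wrist-to-pinky-base vectors). Serves as a model-free oracle for the
#' inverse-kinematics angles.
#'
#' @param track a [track3d()].
#' @param skeleton a hand skeleton (provides the landmark/joint layout).
#' @return a [joint_angle_series()] (NaN where any defining landmark is
#'   invisible).
#' @export
direct_joint_angles <- function(track, skeleton) {
  idx <- match_landmarks(track, skeleton)
  TT <- n_frames(track)
  chains <- digit_chains()
  get <- function(l) matrix(track$data[, idx[l], ], ncol = 3)
  wrist <- get(1)
  nrm <- vcross(get(chains[[2]][1]) - wrist, get(chains[[5]][1]) - wrist)
  nn <- row_norms(nrm)
  nrm <- nrm / ifelse(nn > 0, nn, NA)
  angles <- matrix(NaN, TT, 15)
  warned <- FALSE
  for (j in seq_len(nrow(skeleton$joints))) {
    jt <- skeleton$joints[j, ]
    ch <- chains[[jt$digit]]
    prox_lm <- if (jt$level == 1) 1L else ch[jt$level - 1]
    cen_lm <- ch[jt$level]
    dist_lm <- ch[jt$level + 1]
    v1 <- get(cen_lm) - get(prox_lm)
    v2 <- get(dist_lm) - get(cen_lm)
    n1 <- row_norms(v1); n2 <- row_norms(v2)
    deg <- n1 < 1e-9 | n2 < 1e-9
    if (any(deg, na.rm = TRUE) && !warned) {
      warning("degenerate zero-length bone encountered; angles set to NaN")
      warned <- TRUE
    }
    cr <- vcross(v1, v2)
    theta <- atan2(row_norms(cr), rowSums(v1 * v2))
    # hinge-axis reference from the rigid palm ray of the digit (stays in
    # the palm plane regardless of finger flexion, so the sign is stable
    # even when a bone is perpendicular to the palm)
    ray <- get(ch[1]) - wrist
    axis <- vcross(nrm, ray)
    s <- sign(rowSums(cr * axis))
    s[s == 0 | !is.finite(s)] <- 1
    ang <- theta * s * RAD2DEG
    ang[deg] <- NaN
    angles[, j] <- ang
  }
  joint_angle_series(angles, joint_names = skeleton$joints$name,
                     fs = track$fs, t0 = track$t0)
}

# Row-wise cross product of two n x 3 matrices.
vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Initial pose for the first frame: rigid palm fit (Kabsch over wrist + digit
# bases) for the global DOFs, direct angles for the flexions, abduction 0.
init_pose_from_frame <- function(skeleton, pts, vis, direct_row) {
  q <- numeric(26)
  palm <- c(1L, vapply(digit_chains(), function(ch) as.integer(ch[1]), integer(1)))
  pv <- palm[palm %in% vis]
  if (length(pv) >= 3) {
    fit <- kabsch(skeleton$rest_points[pv, , drop = FALSE],
                  pts[pv, , drop = FALSE])
    q[1:3] <- fit$translation
    q[4:6] <- euler_from_matrix(fit$rotation)
  } else if (1L %in% vis) {
    q[1:3] <- pts[1L, ]
  }
  flex <- direct_row
  flex[!is.finite(flex)] <- 0
  q[skeleton$joints$flex_dof] <- flex
  clamp_pose(skeleton, q)
}

#' Weighted inverse kinematics
#'
#' Per frame, minimizes the weighted sum of squared distances between the
#' model landmarks and the observed ones (invisible landmarks dropped) over
#' the 26-DOF pose by damped least squares (Levenberg-Marquardt with
#' analytic Jacobian and step acceptance, so the cost is non-increasing).
#' Frames are initialized from the previous frame's solution; the first
#' frame from a rigid palm fit plus [direct_joint_angles()]. Box joint
#' limits are enforced by projection.
#'
#' @param track a [track3d()] of observed landmarks (mm).
#' @param skeleton a (scaled) hand skeleton.
#' @param weights per-landmark weights, named or in skeleton landmark order;
#'   default [default_ik_weights()].
#' @param max_iter maximum LM iterations per frame (default 50).
#' @param tol convergence threshold on the cost improvement (mm^2,
#'   default 1e-6).
#' @param trace if TRUE, keep the per-iteration cost of every frame.
#' @return an object of class `hand_ik`: list with `angles` (a
#'   [joint_angle_series()] of the 15 flexion DOFs; invalid where fewer than
#'   4 landmarks are visible or the frame failed to converge), `poses`
#'   (T x 26 matrix), `converged`, `cost` (final weighted cost per frame,
#'   mm^2), and optionally `cost_trace`.
#' @export
inverse_kinematics <- function(track, skeleton, weights = default_ik_weights(skeleton),
                               max_iter = 50, tol = 1e-6, trace = FALSE) {
  idx <- match_landmarks(track, skeleton)
  TT <- n_frames(track)
  if (!is.null(names(weights)))
    weights <- weights[skeleton$landmark_names]
  stopifnot(length(weights) == 21, all(weights >= 0))
  sqw <- sqrt(weights)
  direct <- direct_joint_angles(track, skeleton)
  poses <- matrix(NA_real_, TT, 26, dimnames = list(NULL, skeleton$dof_names))
  converged <- rep(NA, TT)
  cost <- rep(NA_real_, TT)
  ct <- if (trace) vector("list", TT) else NULL
  q_prev <- NULL
  for (f in seq_len(TT)) {
    pts <- matrix(track$data[f, idx, ], ncol = 3)
    vis <- which(track$visible[f, idx])
    if (length(vis) < 4) next
    q <- if (is.null(q_prev))
      init_pose_from_frame(skeleton, pts, vis, direct$angles[f, ])
    else q_prev
    sw <- sqw[vis]
    target <- pts[vis, , drop = FALSE] * sw
    fk <- fk_eval(skeleton, q, check = FALSE, with_axes = TRUE)
    attr(fk, "global_axes") <- global_rotation_axes(q)
    resid <- fk$points[vis, , drop = FALSE] * sw - target
    cst <- sum(resid^2)
    trace_f <- cst
    lambda <- 1e-3
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      J <- ik_jacobian(skeleton, fk, vis, sw)
      g <- crossprod(J, as.numeric(t(resid)))
      H <- crossprod(J)
      improved <- FALSE
      for (try in 1:8) {
        D <- diag(pmax(diag(H), 1e-8)) * lambda
        step <- tryCatch(solve(H + D, -g), error = function(e) NULL)
        if (is.null(step)) { lambda <- lambda * 10; next }
        q_new <- clamp_pose(skeleton, q + as.numeric(step))
        fk_new <- fk_eval(skeleton, q_new, check = FALSE, with_axes = TRUE)
        attr(fk_new, "global_axes") <- global_rotation_axes(q_new)
        resid_new <- fk_new$points[vis, , drop = FALSE] * sw - target
        cst_new <- sum(resid_new^2)
        if (cst_new < cst) {
          improved <- TRUE
          lambda <- max(lambda / 3, 1e-9)
          gain <- cst - cst_new
          q <- q_new; fk <- fk_new; resid <- resid_new; cst <- cst_new
          trace_f <- c(trace_f, cst)
          if (gain < tol) ok <- TRUE
          break
        }
        lambda <- lambda * 10
      }
      if (!improved) { ok <- TRUE; break }  # no descent direction: at a minimum
      if (ok) break
    }
    poses[f, ] <- q
    converged[f] <- ok
    cost[f] <- cst
    if (trace) ct[[f]] <- trace_f
    q_prev <- q
  }
  n_fail <- sum(!converged, na.rm = TRUE)
  if (n_fail > 0)
    message(sprintf("inverse_kinematics: %d frame(s) did not converge", n_fail))
  valid <- !is.na(converged) & converged
  angles <- poses[, skeleton$joints$flex_dof, drop = FALSE]
  angles[!valid, ] <- NaN
  res <- structure(
    list(angles = joint_angle_series(angles, joint_names = skeleton$joints$name,
                                     valid = matrix(valid, TT, 15),
                                     fs = track$fs, t0 = track$t0),
         poses = poses, converged = converged, cost = cost,
         skeleton = skeleton, weights = weights),
    class = "hand_ik")
  if (trace) res$cost_trace <- ct
  res
}

#' @export
print.hand_ik <- function(x, ...) {
  ok <- sum(x$converged, na.rm = TRUE)
  cat(sprintf("<hand_ik> %d frames (%d converged), median cost %.4g mm^2\n",
              length(x$converged), ok, stats::median(x$cost, na.rm = TRUE)))
  invisible(x)
}

#' IK marker residuals
#'
#' Per landmark, the RMSE over visible frames of the distance between the
#' model landmark after IK and the observed landmark.
#'
#' @param track the observed [track3d()] the IK was fit to.
#' @param skeleton the skeleton used for the fit.
#' @param poses a T x 26 pose matrix or a `hand_ik` object.
#' @return list with `per_landmark` (named numeric(21), mm) and `mean`
#'   (grand mean over landmarks with support).
#' @export
ik_residual <- function(track, skeleton, poses) {
  if (inherits(poses, "hand_ik")) poses <- poses$poses
  stopifnot(nrow(poses) == n_frames(track))
  idx <- match_landmarks(track, skeleton)
  sums <- numeric(21); counts <- integer(21)
  for (f in seq_len(nrow(poses))) {
    if (anyNA(poses[f, ])) next
    pts <- forward_kinematics(skeleton, poses[f, ], check = FALSE)
    obs <- matrix(track$data[f, idx, ], ncol = 3)
    vis <- track$visible[f, idx]
    d2 <- rowSums((pts - obs)^2)
    sums[vis] <- sums[vis] + d2[vis]
    counts[vis] <- counts[vis] + 1L
  }
  per <- ifelse(counts > 0, sqrt(sums / counts), NaN)
  names(per) <- skeleton$landmark_names
  list(per_landmark = per, mean = mean(per[counts > 0]))
}

#' Build a 3D track by forward kinematics over a pose series
#'
#' @param skeleton a hand skeleton.
#' @param poses T x 26 matrix of poses.
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds.
#' @return a fully visible [track3d()].
#' @export
fk_track <- function(skeleton, poses, fs = 30, t0 = 0) {
  TT <- nrow(poses)
  data <- array(NA_real_, c(TT, 21, 3))
  for (f in seq_len(TT))
    data[f, , ] <- forward_kinematics(skeleton, poses[f, ])
  track3d(data, landmark_names = skeleton$landmark_names, fs = fs, t0 = t0)
}
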