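# Articulated hand skeleton: 21 landmarks, 20 rigid segments (5 palm rays +
# 15 phalanges), 15 named joints, 26 degrees of freedom (6 global + 4 per
# digit). The palm (wrist + 5 digit bases) is rigid; each digit is a serial
# chain with base flexion + abduction and middle/distal hinge flexion.
#
# Rest geometry: wrist at the origin, digits radiating in the z = 0 plane
# (each digit's phalanges collinear with its palm ray, so 0 deg = straight
# chain), dorsal palm normal along +z for a right hand. Positive flexion
# bends fingertips toward the palmar side (-z).

#' The 15 hand joint names
#'
#' Thumb: 1cmc, 1mp, 1ip. Fingers (digits 2-5): Nmcp, Npm (PIP), Nmd (DIP).
#'
#' @return character(15) in digit-then-proximal-to-distal order.
#' @export
hand_joint_names <- function() {
  c("1cmc", "1mp", "1ip",
    "2mcp", "2pm", "2md",
    "3mcp", "3pm", "3md",
    "4mcp", "4pm", "4md",
    "5mcp", "5pm", "5md")
}

# Per-digit landmark chains in the 21-landmark convention (1-based indices):
# base landmark then successive phalanx endpoints.
digit_chains <- function() {
  list(`1` = c(2, 3, 4, 5),      # thumb CMC, MCP, IP, TIP
       `2` = c(6, 7, 8, 9),      # index MCP, PIP, DIP, TIP
       `3` = c(10, 11, 12, 13),
       `4` = c(14, 15, 16, 17),
       `5` = c(18, 19, 20, 21))
}

#' Build the default hand skeleton template
#'
#' Segment rest lengths are published-average adult values (mm). The left
#' hand is the mirror image (x-negated rest geometry) of the right.
#'
#' @param hand `"right"` (default) or `"left"`.
#' @return an object of class `hand_skeleton`.
#' @export
build_default_skeleton <- function(hand = c("right", "left")) {
  hand <- match.arg(hand)
  mirror <- if (hand == "left") -1 else 1
  # splay angle of each digit ray from the middle-finger axis (+y), degrees;
  # positive toward the thumb (radial) side of a right hand
  splay <- c(45, 15, 0, -12, -25) * mirror
  ray_lengths <- c(35, 85, 88, 82, 75)
  phal_lengths <- list(c(45, 32, 25),   # thumb metacarpal head to tip
                       c(45, 25, 22),   # index proximal, middle, distal
                       c(50, 30, 24),
                       c(46, 28, 24),
                       c(36, 20, 20))
  dirs <- vapply(splay, function(s) c(sin(s * DEG2RAD), cos(s * DEG2RAD), 0),
                 numeric(3))
  # dorsal palm normal consistent with cross(index ray, pinky ray)
  nz <- sign(dirs[1, 2] * dirs[2, 5] - dirs[2, 2] * dirs[1, 5])
  normal <- c(0, 0, nz)
  new_hand_skeleton(hand, dirs, ray_lengths, phal_lengths, normal)
}

# Assemble a skeleton from per-digit geometry; shared by the template
# builder and by scale_skeleton().
new_hand_skeleton <- function(hand, dirs, ray_lengths, phal_lengths, normal) {
  lm <- hand_landmarks()
  chains <- digit_chains()

  rest <- matrix(0, 21, 3, dimnames = list(lm, c("x", "y", "z")))
  for (d in 1:5) {
    u <- dirs[, d]
    p <- ray_lengths[d] * u
    rest[chains[[d]][1], ] <- p
    for (j in 1:3) {
      p <- p + phal_lengths[[d]][j] * u
      rest[chains[[d]][j + 1], ] <- p
    }
  }

  seg_parent <- integer(0); seg_child <- integer(0)
  seg_digit <- integer(0); seg_type <- character(0)
  for (d in 1:5) {
    seg_parent <- c(seg_parent, 1L); seg_child <- c(seg_child, chains[[d]][1])
    seg_digit <- c(seg_digit, d); seg_type <- c(seg_type, "ray")
    for (j in 1:3) {
      seg_parent <- c(seg_parent, chains[[d]][j])
      seg_child <- c(seg_child, chains[[d]][j + 1])
      seg_digit <- c(seg_digit, d)
      seg_type <- c(seg_type, c("proximal", "middle", "distal")[j])
    }
  }
  segments <- data.frame(
    name = paste0("d", seg_digit, "_", seg_type),
    parent = seg_parent, child = seg_child, digit = seg_digit,
    type = seg_type,
    rest_length = row_norms(rest[seg_child, , drop = FALSE] -
                            rest[seg_parent, , drop = FALSE]),
    stringsAsFactors = FALSE)
  if (any(segments$rest_length <= 0)) stop("all rest lengths must be positive")

  dof_names <- c("tx", "ty", "tz", "rx", "ry", "rz",
                 unlist(lapply(1:5, function(d)
                   paste0("d", d, "_", c("flex_base", "abd", "flex_mid", "flex_dist")))))
  lower <- c(rep(-Inf, 6), rep(c(-30, -25, -10, -10), 5))
  upper <- c(rep(Inf, 6), rep(c(110, 25, 115, 90), 5))
  names(lower) <- names(upper) <- dof_names

  jn <- hand_joint_names()
  joints <- data.frame(
    name = jn,
    digit = rep(1:5, each = 3),
    level = rep(1:3, 5),
    stringsAsFactors = FALSE)
  joints$landmark <- mapply(function(d, l) chains[[d]][l],
                            joints$digit, joints$level)
  seg_of <- function(d, type) which(segments$digit == d & segments$type == type)
  joints$prox_segment <- mapply(function(d, l)
    seg_of(d, c("ray", "proximal", "middle")[l]), joints$digit, joints$level)
  joints$dist_segment <- mapply(function(d, l)
    seg_of(d, c("proximal", "middle", "distal")[l]), joints$digit, joints$level)
  joints$flex_dof <- 6L + 4L * (joints$digit - 1L) + c(1L, 3L, 4L)[joints$level]
  joints$abd_dof <- ifelse(joints$level == 1L, 6L + 4L * (joints$digit - 1L) + 2L, NA)

  structure(
    list(hand = hand,
         landmark_names = lm,
         segments = segments,
         joints = joints,
         dof_names = dof_names,
         limits_lower = lower,
         limits_upper = upper,
         rest_points = rest,
         digit_dirs = dirs,
         ray_lengths = ray_lengths,
         phal_lengths = phal_lengths,
         normal = normal),
    class = "hand_skeleton")
}

#' @export
print.hand_skeleton <- function(x, ...) {
  cat(sprintf("<hand_skeleton> %s hand, %d landmarks, %d segments, %d joints, %d DOFs\n",
              x$hand, length(x$landmark_names), nrow(x$segments),
              nrow(x$joints), length(x$dof_names)))
  sc <- attr(x, "finger_scales")
  if (!is.null(sc))
    cat("  finger scales:", paste(sprintf("%.3f", sc), collapse = " "), "\n")
  invisible(x)
}

# Indices of skeleton landmarks within a track (by name); error on missing.
match_landmarks <- function(track, skeleton) {
  idx <- match(skeleton$landmark_names, track$landmark_names)
  if (anyNA(idx))
    stop("unknown landmark(s) in track: ",
         paste(skeleton$landmark_names[is.na(idx)], collapse = ", "))
  idx
}

#' Frame-wise segment lengths of a 3D track
#'
#' @param track a [track3d()] whose landmarks cover the skeleton's.
#' @param skeleton a [build_default_skeleton()] skeleton.
#' @return T x 20 matrix of Euclidean segment lengths in mm, NaN where
#'   either endpoint is invisible; columns named after the segments.
#' @export
segment_lengths <- function(track, skeleton) {
  idx <- match_landmarks(track, skeleton)
  seg <- skeleton$segments
  out <- matrix(NaN, n_frames(track), nrow(seg),
                dimnames = list(NULL, seg$name))
  for (s in seq_len(nrow(seg))) {
    a <- idx[seg$parent[s]]; b <- idx[seg$child[s]]
    d <- track$data[, b, , drop = FALSE] - track$data[, a, , drop = FALSE]
    out[, s] <- sqrt(d[, 1, 1]^2 + d[, 1, 2]^2 + d[, 1, 3]^2)
  }
  out
}

#' Scale the skeleton to a participant from a static trial
#'
#' Landmark positions are averaged over the first `window_s` seconds of
#' visible frames. Each digit receives one longitudinal scale factor,
#' (observed chain length) / (template chain length), applied to its three
#' phalanx segments; each palm ray is scaled from the observed wrist-to-base
#' distance. Joints are never moved off the bone axes.
#'
#' @param skeleton template skeleton.
#' @param static_track a [track3d()] of the static task.
#' @param window_s averaging window in seconds (default 5).
#' @return a scaled `hand_skeleton`; the per-digit scales are attached as
#'   attribute `"finger_scales"` and the ray scales as `"ray_scales"`.
#' @export
scale_skeleton <- function(skeleton, static_track, window_s = 5) {
  idx <- match_landmarks(static_track, skeleton)
  nw <- min(n_frames(static_track), max(2L, round(window_s * static_track$fs)))
  vis <- static_track$visible[seq_len(nw), idx, drop = FALSE]
  if (mean(colMeans(vis)) < 0.5)
    stop("insufficient static data: fewer than 50% of frames visible in window")
  avg <- matrix(NA_real_, 21, 3)
  for (l in 1:21) {
    v <- vis[, l]
    if (!any(v)) stop("insufficient static data: landmark ",
                      skeleton$landmark_names[l], " never visible in window")
    avg[l, ] <- colMeans(matrix(static_track$data[seq_len(nw), idx[l], ][v, ],
                                ncol = 3))
  }
  chains <- digit_chains()
  ray_scales <- numeric(5); finger_scales <- numeric(5)
  new_rays <- skeleton$ray_lengths
  new_phal <- skeleton$phal_lengths
  for (d in 1:5) {
    ch <- chains[[d]]
    obs_ray <- sqrt(sum((avg[ch[1], ] - avg[1, ])^2))
    ray_scales[d] <- obs_ray / skeleton$ray_lengths[d]
    obs_chain <- sum(row_norms(avg[ch[-1], , drop = FALSE] -
                               avg[ch[-4], , drop = FALSE]))
    finger_scales[d] <- obs_chain / sum(skeleton$phal_lengths[[d]])
    new_rays[d] <- obs_ray
    new_phal[[d]] <- skeleton$phal_lengths[[d]] * finger_scales[d]
  }
  out <- new_hand_skeleton(skeleton$hand, skeleton$digit_dirs,
                           new_rays, new_phal, skeleton$normal)
  attr(out, "finger_scales") <- finger_scales
  attr(out, "ray_scales") <- ray_scales
  out
}
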