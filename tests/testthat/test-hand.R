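test_that("the default skeleton template is structurally sound", {
  sk <- build_default_skeleton()
  expect_equal(nrow(sk$segments), 20)
  expect_equal(nrow(sk$joints), 15)
  expect_true(all(sk$segments$rest_length > 0))
  # middle-finger chain outreaches the pinky chain
  expect_gt(sum(sk$phal_lengths[[3]]), sum(sk$phal_lengths[[5]]))
  # segment graph is a tree rooted at the wrist: every non-wrist landmark
  # is the child of exactly one segment
  expect_equal(sort(sk$segments$child), 2:21)

  left <- build_default_skeleton("left")
  expect_equal(left$rest_points[, 1], -sk$rest_points[, 1])
  expect_equal(left$rest_points[, 2:3], sk$rest_points[, 2:3])
})

test_that("segment lengths are Euclidean with NaN under occlusion", {
  sk <- build_default_skeleton()
  data <- array(NaN, c(2, 21, 3))
  data[, 1, ] <- 0
  data[1, 2, ] <- c(3, 4, 0)   # 3-4-5 triangle on the wrist-thumb ray
  data[2, 2, ] <- c(3, 4, 0)
  tr <- track3d(data, fs = 30)
  sl <- segment_lengths(tr, sk)
  expect_equal(sl[1, "d1_ray"], 5, ignore_attr = TRUE)
  expect_true(all(is.nan(sl[, "d2_proximal"])))

  # FK-generated tracks are rigid: lengths equal rest lengths every frame
  qs <- matrix(0, 3, 26, dimnames = list(NULL, sk$dof_names))
  qs[2, c("d2_flex_base", "d3_flex_mid")] <- c(40, 70)
  qs[3, c("rx", "tz", "d5_abd")] <- c(25, 100, -15)
  fk <- fk_track(sk, qs, fs = 30)
  sl2 <- segment_lengths(fk, sk)
  for (f in 1:3)
    expect_equal(unname(sl2[f, ]), sk$segments$rest_length, tolerance = 1e-9)
})

test_that("skeleton scaling recovers constructed per-finger scales", {
  sk <- build_default_skeleton()
  scales <- c(1.1, 0.9, 1.0, 1.0, 1.2)
  scaled <- handmocap:::new_hand_skeleton(
    sk$hand, sk$digit_dirs, sk$ray_lengths * scales,
    Map(`*`, sk$phal_lengths, scales), sk$normal)
  static <- fk_track(scaled, matrix(0, 160, 26), fs = 30)
  rec <- scale_skeleton(sk, static)
  expect_equal(attr(rec, "finger_scales"), scales, tolerance = 1e-6)
  expect_equal(attr(rec, "ray_scales"), scales, tolerance = 1e-6)

  # identity when the static track comes from the unscaled template
  rec0 <- scale_skeleton(sk, fk_track(sk, matrix(0, 160, 26), fs = 30))
  expect_equal(attr(rec0, "finger_scales"), rep(1, 5), tolerance = 1e-9)

  # scale-equivariance: scaling the static track by s scales every factor by s
  static2 <- static
  static2$data <- static2$data * 1.5
  rec2 <- scale_skeleton(sk, static2)
  expect_equal(attr(rec2, "finger_scales"), scales * 1.5, tolerance = 1e-6)

  # insufficient visibility is an explicit error
  sparse <- static
  sparse$visible[, ] <- FALSE
  sparse$visible[1:10, ] <- TRUE
  expect_error(scale_skeleton(sk, sparse), "insufficient static data")
})

test_that("forward kinematics matches single-rotation arithmetic", {
  sk <- build_default_skeleton()
  q <- stats::setNames(numeric(26), sk$dof_names)
  flat <- forward_kinematics(sk, q)
  expect_equal(unname(flat), unname(sk$rest_points), tolerance = 1e-12)

  # index base flexion 90 deg: PIP = MCP + L1 * (rest direction rotated
  # 90 deg about the MCP hinge axis)
  q2 <- q; q2["d2_flex_base"] <- 90
  pts <- forward_kinematics(sk, q2)
  u <- sk$digit_dirs[, 2]
  axis <- c(sk$normal[2] * u[3] - sk$normal[3] * u[2],
            sk$normal[3] * u[1] - sk$normal[1] * u[3],
            sk$normal[1] * u[2] - sk$normal[2] * u[1])
  R <- handmocap:::rotation_about(axis, pi / 2)
  expected <- sk$rest_points["INDEX_FINGER_MCP", ] +
    sk$phal_lengths[[2]][1] * as.numeric(R %*% u)
  expect_equal(unname(pts["INDEX_FINGER_PIP", ]), unname(expected),
               tolerance = 1e-9)

  # translation equivariance
  q3 <- q2; q3[1:3] <- c(10, 0, 0)
  expect_equal(forward_kinematics(sk, q3), pts + rep(c(10, 0, 0), each = 21),
               tolerance = 1e-12)

  # out-of-limit DOFs are rejected with the offender named
  q4 <- q; q4["d3_flex_mid"] <- 170
  expect_error(forward_kinematics(sk, q4), "d3_flex_mid")
})

test_that("direct joint angles agree with FK hinge DOFs at zero abduction", {
  sk <- build_default_skeleton()
  q <- stats::setNames(numeric(26), sk$dof_names)
  tr0 <- fk_track(sk, rbind(q), fs = 30)
  da0 <- direct_joint_angles(tr0, sk)
  expect_lt(max(abs(da0$angles)), 1e-6)

  q["d2_flex_mid"] <- 60   # index PIP (2pm)
  q["d4_flex_base"] <- 45
  q["d1_flex_dist"] <- -10
  q["rx"] <- 20; q["rz"] <- -35; q[1:3] <- c(15, -8, 40)
  tr <- fk_track(sk, rbind(q), fs = 30)
  da <- direct_joint_angles(tr, sk)
  expect_equal(da$angles[1, "2pm"], 60, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(da$angles[1, "4mcp"], 45, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(da$angles[1, "1ip"], -10, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(da$angles[1, c("3mcp", "3pm", "3md")])), 1e-6)

  # invisible defining landmark gives NaN at that joint
  tr$visible[1, match("INDEX_FINGER_DIP", hand_landmarks())] <- FALSE
  tr$data[1, match("INDEX_FINGER_DIP", hand_landmarks()), ] <- NaN
  da2 <- direct_joint_angles(tr, sk)
  expect_true(is.nan(da2$angles[1, "2pm"]))
  expect_true(is.nan(da2$angles[1, "2md"]))
})

test_that("IK recovers poses exactly on noiseless FK data", {
  sk <- build_default_skeleton()
  tt <- seq(0, 1, length.out = 15)
  qs <- matrix(0, 15, 26, dimnames = list(NULL, sk$dof_names))
  qs[, "d2_flex_base"] <- 50 * sin(pi * tt)
  qs[, "d2_abd"] <- 12 * sin(pi * tt)
  qs[, "d3_flex_mid"] <- 80 * sin(pi * tt)
  qs[, "d5_flex_dist"] <- 30 * sin(pi * tt)
  qs[, "rx"] <- 15 * tt; qs[, "tx"] <- 25 * tt
  tr <- fk_track(sk, qs, fs = 30)
  fit <- inverse_kinematics(tr, sk)
  expect_true(all(fit$converged))
  gt <- qs[, sk$joints$flex_dof]
  expect_lt(max(abs(fit$angles$angles - gt)), 0.1)
  res <- ik_residual(tr, sk, fit)
  expect_lt(max(res$per_landmark), 0.1)
})

test_that("IK cost is non-increasing within every frame", {
  sk <- build_default_skeleton()
  cfg <- synthetic_task_config("flexion", n_reps = 1, seed = 2)
  mo <- generate_motion(cfg, sk)
  noisy <- mo$track
  set.seed(9)
  noisy$data <- noisy$data + array(stats::rnorm(length(noisy$data), 0, 2),
                                   dim(noisy$data))
  fit <- inverse_kinematics(noisy, sk, trace = TRUE)
  for (tr in fit$cost_trace)
    if (!is.null(tr)) expect_true(all(diff(tr) <= 0))
})

test_that("IK flags frames with too few landmarks and handles occlusion", {
  sk <- build_default_skeleton()
  qs <- matrix(0, 6, 26, dimnames = list(NULL, sk$dof_names))
  tr <- fk_track(sk, qs, fs = 30)
  tr$visible[3, 1:18] <- FALSE   # 3 landmarks left
  for (k in 1:3) tr$data[3, 1:18, k] <- NaN
  fit <- inverse_kinematics(tr, sk)
  expect_false(any(fit$angles$valid[3, ]))
  expect_true(all(is.nan(fit$angles$angles[3, ])))
  expect_true(all(fit$angles$valid[-3, ]))
})

test_that("IK marker residual equals a constant displacement", {
  sk <- build_default_skeleton()
  qs <- matrix(0, 5, 26, dimnames = list(NULL, sk$dof_names))
  tr <- fk_track(sk, qs, fs = 30)
  fit <- inverse_kinematics(tr, sk)
  moved <- tr
  moved$data[, , 1] <- moved$data[, , 1] + 2
  res <- ik_residual(moved, sk, fit)
  expect_equal(unname(res$per_landmark), rep(2, 21), tolerance = 1e-3)
})
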