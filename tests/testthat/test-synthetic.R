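test_that("task presets honour their defining properties", {
  sk <- build_default_skeleton()
  # static: all angles zero, RoM zero
  st <- generate_motion(synthetic_task_config("static"), sk)
  expect_true(all(st$angles$angles == 0))
  expect_equal(as.numeric(range_of_motion(st$angles)), rep(0, 15),
               tolerance = 1e-12)

  # flexion: RoM at every finger MCP equals the base amplitude
  fl <- generate_motion(synthetic_task_config("flexion"), sk)
  rom <- range_of_motion(fl$angles)
  expect_equal(unname(rom[c("2mcp", "3mcp", "4mcp", "5mcp")]), rep(80, 4),
               tolerance = 1)

  # piano: sequential pinky-to-thumb, at most one finger flexed at a time
  pi_ <- generate_motion(synthetic_task_config("piano"), sk)
  base <- pi_$poses[, paste0("d", 1:5, "_flex_base")]
  expect_lte(max(rowSums(base > 10)), 1)
  # pinky peaks before the thumb within the first repetition
  expect_lt(which.max(pi_$poses[1:60, "d5_flex_base"]),
            which.max(pi_$poses[1:60, "d1_flex_base"]))

  # unknown task is rejected
  expect_error(synthetic_task_config("juggling"), "arg")
})

test_that("generated motion is self-consistent with the direct-angle oracle", {
  sk <- build_default_skeleton()
  for (task in c("flexion", "extension")) {
    mo <- generate_motion(synthetic_task_config(task, n_reps = 2), sk)
    da <- direct_joint_angles(mo$track, sk)
    expect_lt(max(abs(da$angles - mo$angles$angles)), 1e-6)
  }
})

test_that("virtual rigs view the workspace with distinct axes and serialize", {
  for (n in c(2, 4, 6)) {
    rig <- make_rig(n)
    expect_length(rig$cameras, n)
    for (cam in rig$cameras) {
      px <- project(c(0, 0, 1e-9), cam)
      expect_true(all(px >= 0 & px <= cam$image_size))
    }
    axes <- sapply(rig$cameras, function(cam) cam$rotation[3, ])
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ang <- acos(min(1, sum(axes[, i] * axes[, j]))) * 180 / pi
      expect_gte(ang, 20)
    }
  }
  rig <- make_rig(4)
  path <- withr::local_tempfile(fileext = ".json")
  save_rig(rig, path)
  back <- load_rig(path)
  for (nm in names(rig$cameras))
    expect_identical(back$cameras[[nm]]$rotation, rig$cameras[[nm]]$rotation)
})

test_that("rendering injects the configured noise and dropouts", {
  sk <- build_default_skeleton()
  rig <- make_rig(4)
  # sigma = 0, no occlusion: exact noiseless inverse
  cfg0 <- synthetic_task_config("static", duration_s = 2, seed = 0)
  mo <- generate_motion(cfg0, sk)
  t3 <- triangulate_tracks(render_views(mo$track, rig, cfg0), rig)
  expect_lt(max(abs(t3$data - mo$track$data)), 1e-6)

  # sigma = 2 px: empirical residual s.d. in [1.8, 2.2] over 10 seeds
  sds <- sapply(0:9, function(s) {
    cfgN <- synthetic_task_config("static", duration_s = 2, noise_px = 2,
                                  seed = s)
    noisy <- render_views(mo$track, rig, cfgN)[[1]]
    clean <- render_views(mo$track, rig,
                          synthetic_task_config("static", duration_s = 2,
                                                seed = s))[[1]]
    stats::sd(noisy$data - clean$data, na.rm = TRUE)
  })
  expect_true(all(sds > 1.8 & sds < 2.2))

  # occlusion rate 0.2: confidence-zero fraction 0.2 +/- 0.05 over 10 seeds
  fr <- sapply(0:9, function(s) {
    cfgO <- synthetic_task_config("static", duration_s = 10,
                                  occlusion = list(rate = 0.2,
                                                   mean_duration_s = 0.2),
                                  seed = s)
    moO <- generate_motion(cfgO, sk)
    mean(sapply(render_views(moO$track, rig, cfgO),
                function(v) mean(v$confidence == 0)))
  })
  expect_true(all(abs(fr - 0.2) < 0.05))
})

test_that("rendering and simulation are bit-reproducible for a fixed seed", {
  sk <- build_default_skeleton()
  rig <- make_rig(3)
  cfg <- synthetic_task_config("piano", n_reps = 1, noise_px = 1.5,
                               occlusion = list(rate = 0.1, mean_duration_s = 0.2),
                               seed = 123)
  mo <- generate_motion(cfg, sk)
  v1 <- render_views(mo$track, rig, cfg)
  v2 <- render_views(mo$track, rig, cfg)
  expect_identical(v1, v2)
  mo2 <- generate_motion(cfg, sk)
  expect_identical(mo$poses, mo2$poses)
})

test_that("reference occlusion reproduces the requested dropout statistics", {
  sk <- build_default_skeleton()
  mo <- generate_motion(synthetic_task_config("static", duration_s = 30), sk)
  # rate 0: identity
  same <- simulate_reference_occlusion(mo$track, list(rate = 0), seed = 1)
  expect_identical(same$visible, mo$track$visible)
  # grand mean tracks the configured rate (flexion-regime preset 16.6%)
  gm <- sapply(0:9, function(s)
    attr(occlusion_rates(simulate_reference_occlusion(
      mo$track, list(rate = 0.166, duration_s = 0.3, wrist_bias = 1),
      seed = s)), "mean"))
  expect_lt(abs(mean(gm) - 0.166), 0.02)
  # wrist bias x3 concentrates occlusion on wrist/palm landmarks
  wrn <- c("WRIST", "THUMB_CMC", "INDEX_FINGER_MCP", "MIDDLE_FINGER_MCP",
           "RING_FINGER_MCP", "PINKY_MCP")
  rs <- sapply(0:14, function(s) {
    r <- occlusion_rates(simulate_reference_occlusion(
      mo$track, list(rate = 0.08, duration_s = 0.2, wrist_bias = 3), seed = s))
    wr <- names(r) %in% wrn
    c(mean(r[wr]), mean(r[!wr]))
  })
  expect_equal(mean(rs[1, ]) / mean(rs[2, ]), 3, tolerance = 0.25)
})

test_that("the end-to-end synthetic chain recovers ground-truth angles", {
  sk <- build_default_skeleton()
  cfg <- synthetic_task_config("piano", n_reps = 1, seed = 5)
  mo <- generate_motion(cfg, sk)
  t3 <- triangulate_tracks(render_views(mo$track, make_rig(4), cfg), make_rig(4))
  fit <- inverse_kinematics(t3, sk)
  r <- joint_angle_rmse(mo$angles, fit$angles)
  expect_lt(r$mean_rmse, 0.5)
})
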