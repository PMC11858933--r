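test_that("triangulation recovers noiseless points and rejects bad input", {
  rig <- toy_rig(2)
  p <- c(10, 20, 30)
  obs <- lapply(rig$cameras, function(cam) list(cam = cam, px = project(p, cam)))
  expect_equal(triangulate_point(obs), p, tolerance = 1e-6)
  expect_error(triangulate_point(obs[1]), "insufficient views")
})

test_that("triangulation with a perturbed observation matches the grid-search oracle", {
  rig <- toy_rig(4, angles_deg = c(0, 60, 150, 260))
  set.seed(42)
  for (i in 1:10) {
    p <- c(stats::runif(2, -40, 40), stats::runif(1, -20, 20))
    obs <- lapply(rig$cameras, function(cam) list(cam = cam, px = project(p, cam)))
    # one inconsistent ray: shift a single camera's observation by +5 px in x
    k <- sample(length(obs), 1)
    obs[[k]]$px <- obs[[k]]$px + c(5, 0)
    dlt <- triangulate_point(obs)
    oracle <- grid_search_point(obs, center = p, half_width = 25)
    expect_lt(sqrt(sum((dlt - oracle)^2)), 0.5)
  }
})

test_that("track triangulation gates on confidence and validates inputs", {
  sk <- build_default_skeleton()
  rig <- make_rig(4)
  cfg <- synthetic_task_config("piano", n_reps = 1, seed = 7)
  mo <- generate_motion(cfg, sk)
  views <- render_views(mo$track, rig, cfg)
  t3 <- triangulate_tracks(views, rig)
  expect_true(all(t3$visible))
  expect_lt(max(abs(t3$data - mo$track$data)), 1e-6)

  # landmark observed by fewer than 2 confident views becomes invisible
  views2 <- views
  for (c in 1:3) views2[[c]]$confidence[10:20, 5] <- 0
  t3b <- triangulate_tracks(views2, rig)
  expect_false(any(t3b$visible[10:20, 5]))
  expect_true(all(is.nan(t3b$data[10:20, 5, ])))

  # mixed frame counts are a track mismatch
  short <- views
  short[[1]]$data <- short[[1]]$data[1:10, , , drop = FALSE]
  short[[1]]$confidence <- short[[1]]$confidence[1:10, , drop = FALSE]
  expect_error(triangulate_tracks(short, rig), "track mismatch")
})

test_that("reprojection RMSE is zero for exact data and equals a constant offset", {
  sk <- build_default_skeleton()
  rig <- make_rig(4)
  cfg <- synthetic_task_config("static", duration_s = 2, seed = 1)
  mo <- generate_motion(cfg, sk)
  views <- render_views(mo$track, rig, cfg)
  t3 <- triangulate_tracks(views, rig)
  rp <- reprojection_rmse(t3, views, rig)
  expect_lt(max(rp$px), 1e-9)

  # displace one camera's observations by exactly 3 px in x,
  # keeping the 3D estimate fixed
  shifted <- views
  shifted[[2]]$data[, , 1] <- shifted[[2]]$data[, , 1] + 3
  rp2 <- reprojection_rmse(t3, shifted, rig)
  expect_equal(unname(rp2$px["cam2"]), 3, tolerance = 1e-9)
  expect_lt(max(rp2$px[c("cam1", "cam3", "cam4")]), 1e-9)
})

test_that("per-camera reprojection RMSE sits near the injected noise level", {
  sk <- build_default_skeleton()
  rig <- make_rig(4)
  per_seed <- sapply(0:9, function(s) {
    cfg <- synthetic_task_config("static", duration_s = 2, noise_px = 2, seed = s)
    mo <- generate_motion(cfg, sk)
    views <- render_views(mo$track, rig, cfg)
    t3 <- triangulate_tracks(views, rig)
    reprojection_rmse(t3, views, rig)$px
  })
  expect_true(all(per_seed >= 1 & per_seed <= 3))
})

test_that("anatomical error matches a hand-computed standard-deviation RMS", {
  sk <- build_default_skeleton()
  # only index MCP-PIP and PIP-DIP supported; lengths [10,10,10] and [10,12,14]
  data <- array(NaN, c(3, 21, 3))
  i_mcp <- match("INDEX_FINGER_MCP", hand_landmarks())
  i_pip <- match("INDEX_FINGER_PIP", hand_landmarks())
  i_dip <- match("INDEX_FINGER_DIP", hand_landmarks())
  for (f in 1:3) {
    data[f, i_mcp, ] <- c(0, 0, 0)
    data[f, i_pip, ] <- c(10, 0, 0)
    data[f, i_dip, ] <- c(10 + c(10, 12, 14)[f], 0, 0)
  }
  tr <- track3d(data, fs = 30)
  got <- anatomical_error(tr, sk)
  expect_equal(as.numeric(got), sqrt((0^2 + 2^2) / 2), tolerance = 1e-9)
  expect_equal(length(attr(got, "excluded_segments")), 13)

  # rigid motion has zero anatomical error
  rigid <- fk_track(sk, matrix(0, 5, 26), fs = 30)
  expect_lt(as.numeric(anatomical_error(rigid, sk)), 1e-9)
})

test_that("anatomical error grows monotonically with 2D noise", {
  sk <- build_default_skeleton()
  rig <- make_rig(4)
  means <- sapply(c(0, 2, 5), function(sig) {
    mean(sapply(0:9, function(s) {
      cfg <- synthetic_task_config("static", duration_s = 2, noise_px = sig,
                                   seed = s)
      mo <- generate_motion(cfg, sk)
      t3 <- triangulate_tracks(render_views(mo$track, rig, cfg), rig)
      as.numeric(anatomical_error(t3, sk))
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("subset enumeration covers all sizes in a deterministic order", {
  subs <- enumerate_subsets(4)
  expect_length(subs, 11)  # 6 pairs + 4 triples + 1 quadruple
  sizes <- lengths(subs)
  expect_equal(sizes, sort(sizes, decreasing = TRUE))
  expect_length(enumerate_subsets(2), 1)
  expect_error(enumerate_subsets(1), "at least")
  named <- enumerate_subsets(c("a", "b", "c"))
  expect_equal(named[[1]], c("a", "b", "c"))
})

test_that("subset selection keeps clean rigs whole and drops a bad camera", {
  sk <- build_default_skeleton()
  rig <- make_rig(4)
  cfg <- synthetic_task_config("flexion", n_reps = 2, noise_px = 1, seed = 11)
  mo <- generate_motion(cfg, sk)
  sel <- select_subset(render_views(mo$track, rig, cfg), rig, sk)
  expect_s3_class(sel, "selection_result")
  expect_equal(sort(sel$chosen$subset), paste0("cam", 1:4))
  expect_equal(sel$reason, "all_pass")

  cfg2 <- synthetic_task_config("flexion", n_reps = 2, noise_px = 1, seed = 11,
                                bad_cameras = list(cam2 = list(sigma_px = 24)))
  mo2 <- generate_motion(cfg2, sk)
  sel2 <- select_subset(render_views(mo2$track, rig, cfg2), rig, sk)
  expect_false("cam2" %in% sel2$chosen$subset)
  expect_equal(sel2$reason, "fallback_smaller")

  # impossible thresholds fall back to the best-effort subset
  sel3 <- select_subset(render_views(mo2$track, rig, cfg2), rig, sk,
                        thresholds = list(reproj_mm = 0, anat_mm = 0))
  expect_equal(sel3$reason, "none_pass_best_effort")
  expect_gte(length(sel3$chosen$subset), 2)
})

test_that("the chosen subset score equals recomputation from scratch", {
  sk <- build_default_skeleton()
  rig <- make_rig(4)
  cfg <- synthetic_task_config("static", duration_s = 2, noise_px = 2, seed = 3)
  mo <- generate_motion(cfg, sk)
  views <- render_views(mo$track, rig, cfg)
  sel <- select_subset(views, rig, sk)
  redo <- handmocap:::score_subset(sel$chosen$subset, views, rig, sk,
                                   sel$thresholds, 0.5)
  expect_equal(sel$chosen$reproj_rmse_px, redo$reproj_rmse_px, tolerance = 1e-12)
  expect_equal(sel$chosen$anatomical_mm, redo$anatomical_mm, tolerance = 1e-12)
  # chosen subset always appears among the scored subsets
  keys <- vapply(sel$all_scores, function(s) paste(s$subset, collapse = ","),
                 character(1))
  expect_true(paste(sel$chosen$subset, collapse = ",") %in% keys)
})
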