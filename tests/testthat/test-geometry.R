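test_that("pinhole projection follows the standard model", {
  cam <- camera_model("c", c(1280, 720), c(1000, 1000), c(640, 360))
  # optical-axis point lands on the principal point
  expect_equal(project(c(0, 0, 500), cam), c(640, 360), tolerance = 1e-12)
  # manual pinhole arithmetic x' = cx + fx * X / Z
  expect_equal(project(c(50, 0, 500), cam), c(740, 360), tolerance = 1e-12)
  expect_error(project(c(0, 0, -10), cam), "behind camera")
})

test_that("projection round-trips through undistortion and handles distortion", {
  cam <- camera_model("c", c(1280, 720), c(950, 980), c(640, 360),
                      distortion = c(-0.1, 0.02, 0.001, -0.002, 0.005))
  pts <- rbind(c(30, -40, 450), c(-80, 55, 600), c(5, 5, 320))
  px <- handmocap:::project_points(pts, cam)
  norm <- handmocap:::undistort_points(px, cam)
  expect_equal(norm, cbind(pts[, 1] / pts[, 3], pts[, 2] / pts[, 3]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("projection is invariant under a common rigid transform", {
  cam <- camera_model("c", c(1280, 720), c(1000, 1000), c(640, 360),
                      rotation = rodrigues_to_matrix(c(0.1, -0.2, 0.3)),
                      translation = c(10, -20, 400))
  point <- c(25, -10, 80)
  base <- project(point, cam)
  Rt <- rodrigues_to_matrix(c(0.4, 0.1, -0.2)); tt <- c(100, -50, 30)
  point2 <- as.numeric(Rt %*% point + tt)
  cam2 <- camera_model("c", cam$image_size, cam$focal, cam$principal_point,
                       rotation = cam$rotation %*% t(Rt),
                       translation = cam$translation -
                         as.numeric(cam$rotation %*% t(Rt) %*% tt))
  expect_equal(project(point2, cam2), base, tolerance = 1e-9)
})

test_that("rodrigues conversions invert each other", {
  for (v in list(c(0, 0, 0), c(0.3, -0.5, 0.2), c(pi - 1e-3, 0, 0))) {
    R <- rodrigues_to_matrix(v)
    expect_equal(rodrigues_to_matrix(matrix_to_rodrigues(R)), R,
                 tolerance = 1e-8)
  }
})

test_that("rig calibration files round-trip exactly and are validated", {
  rig <- toy_rig(4, angles_deg = c(0, 60, 150, 260))
  path <- withr::local_tempfile(fileext = ".json")
  save_rig(rig, path)
  back <- load_rig(path)
  expect_equal(length(back$cameras), 4)
  for (nm in names(rig$cameras)) {
    expect_identical(back$cameras[[nm]]$rotation, rig$cameras[[nm]]$rotation)
    expect_identical(back$cameras[[nm]]$translation, rig$cameras[[nm]]$translation)
    expect_identical(back$cameras[[nm]]$focal, rig$cameras[[nm]]$focal)
  }

  # improper rotation (det -1) is rejected with the camera named
  bad <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  R <- matrix(bad$cameras[[2]]$rotation, 3, 3, byrow = TRUE)
  R[1, ] <- -R[1, ]
  bad$cameras[[2]]$rotation <- as.numeric(t(R))
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE, digits = NA)
  expect_error(load_rig(path2), "cam2.*rotation")

  # missing field and duplicate names are schema errors
  bad2 <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  bad2$cameras[[1]]$translation <- NULL
  path3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad2, path3, auto_unbox = TRUE, digits = NA)
  expect_error(load_rig(path3), "missing field 'translation'")
})

test_that("rig loader accepts rodrigues rotations, K matrices and metre units", {
  rig <- toy_rig(2)
  cam <- rig$cameras[[1]]
  alt <- list(cameras = list(list(
    name = "alt",
    image_size = cam$image_size,
    matrix = as.numeric(t(rbind(c(cam$focal[1], 0, cam$principal_point[1]),
                                c(0, cam$focal[2], cam$principal_point[2]),
                                c(0, 0, 1)))),
    rodrigues = matrix_to_rodrigues(cam$rotation),
    translation = cam$translation / 1000,
    units = "m")))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(alt, path, auto_unbox = TRUE, digits = NA)
  back <- load_rig(path)$cameras[[1]]
  expect_equal(back$rotation, cam$rotation, tolerance = 1e-9)
  expect_equal(back$translation, cam$translation, tolerance = 1e-9)
  expect_equal(back$focal, cam$focal)
})
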