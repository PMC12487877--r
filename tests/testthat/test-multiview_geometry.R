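test_that("camera models validate intrinsics and rotation", {
  K <- matrix(c(1000, 0, 320, 0, 1000, 240, 0, 0, 1), 3, 3, byrow = TRUE)
  cm <- camera_model(K)
  expect_s3_class(cm, "qdpi_camera")
  expect_equal(cm$dist, rep(0, 5))
  Kbad <- K; Kbad[2, 1] <- 5
  expect_error(camera_model(Kbad), "upper-triangular")
  expect_error(camera_model(K, R = diag(3) * 2), "orthonormal")
  expect_error(camera_model(K, pixel_pitch_um = -1), "positive")
})

test_that("distortion and undistortion are inverse operations", {
  dist <- c(-0.2, 0.05, 0.001, -0.002, 0.01)
  set.seed(8)
  xy <- cbind(runif(50, -0.3, 0.3), runif(50, -0.3, 0.3))
  xyd <- qdpi:::.distort(xy, dist)
  back <- qdpi:::.undistort(xyd, dist)
  expect_equal(back, xy, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("noiseless multiview triangulation recovers the point exactly", {
  rig <- simulate_camera_rig(sim_config(seed = 19), n_points = 8)
  for (f in c(0, 3, 7)) {
    obs <- rig$keypoints[rig$keypoints$frame == f, c("camera", "x", "y")]
    tp <- triangulate(obs, rig$cameras)
    truth <- as.numeric(rig$points3d[rig$points3d$frame == f, c("X", "Y", "Z")])
    expect_lt(sqrt(sum((tp$position - truth)^2)), 1e-6)
    expect_lt(max(tp$per_view$reproj_px), 1e-6)
    expect_false(tp$degenerate)
    expect_equal(tp$n_views, 5L)
  }
  expect_error(triangulate(rig$keypoints[1, c("camera", "x", "y")], rig$cameras),
               "at least 2")
})

test_that("triangulation also inverts distorted projections", {
  K <- matrix(c(1400, 0, 319.5, 0, 1400, 239.5, 0, 0, 1), 3, 3, byrow = TRUE)
  dist <- c(-0.15, 0.03, 0.001, 0.002, 0)
  cams <- list(
    a = camera_model(K, dist, R = diag(3), t = c(0, 0, 400)),
    b = camera_model(K, dist,
                     R = matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE),
                     t = c(0, 0, 400))
  )
  X <- c(12, -20, 35)
  obs <- dplyr::bind_rows(lapply(names(cams), function(nm) {
    pr <- project_points(cams[[nm]], X)
    tibble::tibble(camera = nm, x = pr$x, y = pr$y)
  }))
  tp <- triangulate(obs, cams)
  expect_lt(sqrt(sum((tp$position - X)^2)), 1e-6)
})

test_that("triangulation is invariant to a common rigid transform", {
  rig <- simulate_camera_rig(sim_config(seed = 20), n_points = 4)
  obs <- rig$keypoints[rig$keypoints$frame == 2, c("camera", "x", "y")]
  p0 <- triangulate(obs, rig$cameras)$position
  # rotate and translate the whole scene
  th <- 0.7
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  shift <- c(100, -50, 30)
  cams2 <- lapply(rig$cameras, function(cm) {
    camera_model(cm$K, cm$dist, R = cm$R %*% t(Q),
                 t = cm$t - as.numeric(cm$R %*% t(Q) %*% shift),
                 pixel_pitch_um = cm$pixel_pitch_um,
                 focal_length_mm = cm$focal_length_mm)
  })
  p1 <- triangulate(obs, cams2)$position
  expect_equal(as.numeric(Q %*% p0 + shift), p1, tolerance = 1e-6)
})

test_that("near-parallel rays are flagged degenerate", {
  K <- matrix(c(1400, 0, 319.5, 0, 1400, 239.5, 0, 0, 1), 3, 3, byrow = TRUE)
  cams <- list(
    a = camera_model(K, t = c(0, 0, 400)),
    b = camera_model(K, t = c(0, 0, 400.001))  # nearly identical viewpoint
  )
  obs <- tibble::tibble(camera = c("a", "b"), x = 320, y = 240)
  expect_true(triangulate(obs, cams)$degenerate)
})

test_that("noisy triangulation matches a dense grid search within 10%", {
  rig <- simulate_camera_rig(sim_config(seed = 33, camera_px_noise = 0.5),
                             n_points = 4)
  cams <- rig$cameras
  errs_dlt <- errs_grid <- numeric(4)
  for (f in 0:3) {
    obs <- rig$keypoints[rig$keypoints$frame == f, c("camera", "x", "y")]
    truth <- as.numeric(rig$points3d[rig$points3d$frame == f, c("X", "Y", "Z")])
    tp <- triangulate(obs, cams)
    errs_dlt[f + 1] <- sqrt(sum((tp$position - truth)^2))
    # brute-force reprojection minimizer on a small grid around the truth
    grid <- expand.grid(X = truth[1] + seq(-0.8, 0.8, 0.02),
                        Y = truth[2] + seq(-0.8, 0.8, 0.02),
                        Z = truth[3] + seq(-0.8, 0.8, 0.02))
    cost <- rep(0, nrow(grid))
    for (ci in obs$camera) {
      pr <- project_points(cams[[ci]], as.matrix(grid))
      o <- obs[obs$camera == ci, ]
      cost <- cost + (pr$x - o$x)^2 + (pr$y - o$y)^2
    }
    best <- as.numeric(grid[which.min(cost), ])
    errs_grid[f + 1] <- sqrt(sum((best - truth)^2))
  }
  expect_lt(abs(mean(errs_dlt) - mean(errs_grid)),
            0.1 * max(mean(errs_grid), mean(errs_dlt)))
})

test_that("camera distance and angle match explicit vector algebra", {
  K <- matrix(c(1000, 0, 320, 0, 1000, 240, 0, 0, 1), 3, 3, byrow = TRUE)
  cm <- camera_model(K, t = c(0, 0, 500))  # center at origin... axis +z
  # camera center C = -R't = (0, 0, -500); axis = +z
  da <- camera_distance_angle(c(0, 0, 100), cm)
  expect_equal(da$distance_mm, 600)
  expect_equal(da$angle_deg, 0)
  set.seed(3)
  for (i in 1:5) {
    X <- runif(3, -100, 100)
    da <- camera_distance_angle(X, cm)
    C <- c(0, 0, -500)
    ray <- X - C
    expect_equal(da$distance_mm, sqrt(sum(ray^2)))
    expect_equal(da$angle_deg,
                 acos(sum(ray * c(0, 0, 1)) / sqrt(sum(ray^2))) * 180 / pi)
  }
  expect_error(camera_distance_angle(c(0, 0, -500), cm), "camera center")
})

test_that("pixel-to-millimeter conversion follows the pinhole footprint", {
  expect_equal(pixels_to_mm(0, 304.8, 8, 5.7), 0)
  expect_equal(pixels_to_mm(1, 304.8, 8, 5.7), 0.21717)
  expect_equal(pixels_to_mm(1, 609.6, 8, 5.7), 2 * 0.21717)  # linear in distance
  expect_equal(mm_to_pixels(pixels_to_mm(3.7, 304.8, 8, 5.7), 304.8, 8, 5.7), 3.7)
  expect_error(pixels_to_mm(1, -1, 8, 5.7), "positive")
})

test_that("the Nyquist limit is twice the one-pixel footprint", {
  expect_equal(nyquist_limit(5.7, 304.8, 8), 0.43434)
  expect_equal(nyquist_limit(5.7, 304.8, 8), 2 * pixels_to_mm(1, 304.8, 8, 5.7))
  expect_equal(nyquist_limit(5.7 / 2, 304.8, 8), 0.43434 / 2)
})

test_that("triangulate_keypoints maps a whole table", {
  rig <- simulate_camera_rig(sim_config(seed = 3), n_points = 5)
  out <- triangulate_keypoints(rig$keypoints, rig$cameras)
  expect_equal(nrow(out), 5L)
  expect_lt(max(abs(out$X - rig$points3d$X)), 1e-6)
  expect_true(all(out$n_views == 5))
})
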