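#' Calibrated pinhole camera model
#'
#' Intrinsics, radial-tangential distortion and world-to-camera extrinsics.
#' World units are millimeters throughout, which keeps pixel-to-millimeter
#' error conversion unambiguous.
#'
#' @param K 3x3 intrinsic matrix (px): upper-triangular, positive focal terms.
#' @param dist Distortion coefficients `(k1, k2, p1, p2, k3)`; shorter vectors
#'   are zero-padded.
#' @param R 3x3 world-to-camera rotation (orthonormal, det +1).
#' @param t Length-3 world-to-camera translation (mm).
#' @param pixel_pitch_um Physical pixel size, micrometers.
#' @param focal_length_mm Lens focal length, millimeters.
#' @return A `qdpi_camera` list.
#' @export
camera_model <- function(K, dist = rep(0, 5), R = diag(3), t = c(0, 0, 0),
                         pixel_pitch_um = 5.7, focal_length_mm = 8) {
  K <- matrix(as.numeric(K), 3, 3)
  if (abs(K[2, 1]) > 1e-9 || abs(K[3, 1]) > 1e-9 || abs(K[3, 2]) > 1e-9) {
    abort("intrinsic matrix must be upper-triangular.")
  }
  if (K[1, 1] <= 0 || K[2, 2] <= 0) abort("focal terms of K must be positive.")
  R <- matrix(as.numeric(R), 3, 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    abort("rotation must be orthonormal with det = +1.")
  }
  dist <- as.numeric(dist)
  if (length(dist) > 5L) abort("at most 5 distortion coefficients supported.")
  dist <- c(dist, rep(0, 5 - length(dist)))
  if (pixel_pitch_um <= 0 || focal_length_mm <= 0) {
    abort("pixel pitch and focal length must be positive.")
  }
  structure(
    list(K = K, dist = dist, R = R, t = as.numeric(t),
         pixel_pitch_um = pixel_pitch_um, focal_length_mm = focal_length_mm),
    class = "qdpi_camera"
  )
}

#' @export
print.qdpi_camera <- function(x, ...) {
  cat(sprintf("<qdpi_camera> f = (%.1f, %.1f) px, pp = (%.1f, %.1f), pitch %.2f um, lens %.1f mm\n",
              x$K[1, 1], x$K[2, 2], x$K[1, 3], x$K[2, 3],
              x$pixel_pitch_um, x$focal_length_mm))
  invisible(x)
}

# apply radial-tangential distortion to normalized coordinates (n x 2)
.distort <- function(xy, dist) {
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * radial + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  cbind(xd, yd)
}

# invert distortion by fixed-point iteration on normalized coordinates
.undistort <- function(xy, dist, n_iter = 25L) {
  if (all(dist == 0)) return(xy)
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  xd <- xy[, 1]; yd <- xy[, 2]
  x <- xd; y <- yd
  for (i in seq_len(n_iter)) {
    r2 <- x^2 + y^2
    radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    dx <- 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
    dy <- p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
    x <- (xd - dx) / radial
    y <- (yd - dy) / radial
  }
  cbind(x, y)
}

#' Project world points into a camera
#'
#' @param camera A `qdpi_camera`.
#' @param points n x 3 matrix (or length-3 vector) of world points, mm.
#' @return Tibble with `x`, `y` pixel coordinates (0-based convention) and
#'   `depth` (camera-frame z, mm).
#' @export
project_points <- function(camera, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  pc <- t(camera$R %*% t(points) + camera$t)  # camera frame
  norm_xy <- cbind(pc[, 1] / pc[, 3], pc[, 2] / pc[, 3])
  d <- .distort(norm_xy, camera$dist)
  px <- t(camera$K %*% rbind(t(d), 1))
  tibble::tibble(x = px[, 1], y = px[, 2], depth = pc[, 3])
}

#' Triangulate a point from calibrated multi-view observations
#'
#' Observations are undistorted with each camera's distortion model, then a
#' direct linear transform (singular-value solution minimizing algebraic
#' error) recovers the 3-D point. Per-view reprojection error, distance to
#' each camera center and angle from each optical axis are reported. Geometry
#' is flagged degenerate when all viewing rays are nearly parallel (the
#' linear system cannot resolve depth).
#'
#' @param observations Data frame with `camera`, `x`, `y` (px, one row per
#'   view).
#' @param cameras Named list of `qdpi_camera` objects.
#' @param refine Run one Gauss-Newton reprojection refinement step after the
#'   linear solve (off by default).
#' @return A `qdpi_point3d`: list with `position` (mm, world), `per_view`
#'   tibble (`camera`, `reproj_px`, `distance_mm`, `angle_deg`), `n_views`,
#'   `degenerate`.
#' @export
triangulate <- function(observations, cameras, refine = FALSE) {
  observations <- tibble::as_tibble(observations)
  if (nrow(observations) < 2L) abort("triangulation needs at least 2 views.")
  miss <- setdiff(unique(observations$camera), names(cameras))
  if (length(miss)) abort(paste0("no calibration for camera(s): ",
                                 paste(miss, collapse = ", ")))
  rays <- matrix(NA_real_, nrow(observations), 3)
  A <- matrix(0, 2L * nrow(observations), 4)
  for (i in seq_len(nrow(observations))) {
    cm <- cameras[[observations$camera[i]]]
    pix <- c(observations$x[i], observations$y[i])
    nc <- solve(cm$K, c(pix, 1))
    und <- .undistort(matrix(nc[1:2] / nc[3], 1), cm$dist)
    P <- cbind(cm$R, cm$t)
    A[2L * i - 1L, ] <- und[1] * P[3, ] - P[1, ]
    A[2L * i, ] <- und[2] * P[3, ] - P[2, ]
    rays[i, ] <- t(cm$R) %*% c(und[1], und[2], 1)  # ray direction, world frame
    rays[i, ] <- rays[i, ] / sqrt(sum(rays[i, ]^2))
  }
  max_angle <- 0
  for (i in seq_len(nrow(rays) - 1L)) {
    for (j in (i + 1L):nrow(rays)) {
      ca <- abs(sum(rays[i, ] * rays[j, ]))
      max_angle <- max(max_angle, acos(pmin(pmax(ca, -1), 1)))
    }
  }
  degenerate <- max_angle < 1e-3  # all rays within ~0.06 degrees
  sv <- svd(A)
  h <- sv$v[, 4]
  if (abs(h[4]) < 1e-12) degenerate <- TRUE
  X <- h[1:3] / h[4]
  if (refine && !degenerate) X <- .refine_point(X, observations, cameras)
  per_view <- purrr::map(seq_len(nrow(observations)), function(i) {
    cm <- cameras[[observations$camera[i]]]
    pr <- project_points(cm, X)
    da <- camera_distance_angle(X, cm)
    tibble::tibble(
      camera = observations$camera[i],
      reproj_px = sqrt((pr$x - observations$x[i])^2 + (pr$y - observations$y[i])^2),
      distance_mm = da$distance_mm,
      angle_deg = da$angle_deg
    )
  }) %>% bind_rows()
  structure(
    list(position = X, per_view = per_view, n_views = nrow(observations),
         degenerate = degenerate),
    class = "qdpi_point3d"
  )
}

# one Gauss-Newton step (numeric Jacobian) on total squared reprojection error
.refine_point <- function(X, observations, cameras) {
  res_fun <- function(p) {
    unlist(lapply(seq_len(nrow(observations)), function(i) {
      pr <- project_points(cameras[[observations$camera[i]]], p)
      c(pr$x - observations$x[i], pr$y - observations$y[i])
    }))
  }
  r0 <- res_fun(X)
  eps <- 1e-4
  J <- vapply(1:3, function(k) {
    dp <- X; dp[k] <- dp[k] + eps
    (res_fun(dp) - r0) / eps
  }, numeric(length(r0)))
  step <- tryCatch(solve(crossprod(J), crossprod(J, r0)), error = function(e) NULL)
  if (is.null(step)) X else X - as.numeric(step)
}

#' @export
print.qdpi_point3d <- function(x, ...) {
  cat(sprintf("<qdpi_point3d> (%.2f, %.2f, %.2f) mm from %d views%s\n",
              x$position[1], x$position[2], x$position[3], x$n_views,
              if (x$degenerate) " [degenerate geometry]" else ""))
  invisible(x)
}

#' @export
tidy.qdpi_point3d <- function(x, ...) x$per_view

#' Distance and optical-axis angle from a camera to a point
#'
#' @param point Length-3 world point (mm).
#' @param camera A `qdpi_camera`.
#' @return One-row tibble: `distance_mm` (camera center to point),
#'   `angle_deg` (between the optical axis and the camera-to-point ray).
#' @export
camera_distance_angle <- function(point, camera) {
  center <- -as.numeric(t(camera$R) %*% camera$t)
  ray <- as.numeric(point) - center
  d <- sqrt(sum(ray^2))
  if (d < 1e-12) abort("point coincides with the camera center; angle undefined.")
  axis <- as.numeric(camera$R[3, ])  # +z of camera, world frame
  ca <- sum(ray * axis) / d
  tibble::tibble(distance_mm = d,
                 angle_deg = acos(pmin(pmax(ca, -1), 1)) * 180 / pi)
}

#' Convert a pixel error to millimeters
#'
#' Pinhole small-angle model: one pixel at object distance `d` spans
#' `pixel_pitch * d / focal_length` millimeters.
#'
#' @param error_px Error in pixels.
#' @param distance_mm Distance from the camera center to the object, mm.
#' @param focal_length_mm Lens focal length, mm.
#' @param pixel_pitch_um Sensor pixel size, micrometers.
#' @return Error in millimeters.
#' @examples
#' pixels_to_mm(1, 304.8, 8, 5.7)  # one-pixel footprint of the standard rig
#' @export
pixels_to_mm <- function(error_px, distance_mm, focal_length_mm, pixel_pitch_um) {
  if (any(distance_mm <= 0) || any(focal_length_mm <= 0) || any(pixel_pitch_um <= 0)) {
    abort("distance, focal length and pixel pitch must be positive.")
  }
  error_px * (pixel_pitch_um / 1000) * distance_mm / focal_length_mm
}

#' @rdname pixels_to_mm
#' @param error_mm Error in millimeters (inverse conversion).
#' @export
mm_to_pixels <- function(error_mm, distance_mm, focal_length_mm, pixel_pitch_um) {
  error_mm / pixels_to_mm(1, distance_mm, focal_length_mm, pixel_pitch_um)
}

#' Optical Nyquist limit of the imaging system
#'
#' Twice the object-plane footprint of one sensor pixel: the smallest
#' resolvable feature size under ideal sampling.
#'
#' @inheritParams pixels_to_mm
#' @param object_distance_mm Distance from the camera to the object, mm.
#' @return Limit in millimeters.
#' @export
nyquist_limit <- function(pixel_pitch_um, object_distance_mm, focal_length_mm) {
  2 * pixels_to_mm(1, object_distance_mm, focal_length_mm, pixel_pitch_um)
}

#' Triangulate every (frame, node) of a multi-camera keypoint table
#'
#' @param table Keypoint table with observations from >= 2 cameras per
#'   (frame, node).
#' @param cameras Named list of `qdpi_camera`.
#' @param refine Passed to [triangulate()].
#' @return Tibble with one row per (frame, node): `X`, `Y`, `Z` (mm),
#'   `n_views`, `degenerate`, `mean_reproj_px`, `mean_distance_mm`,
#'   `mean_angle_deg`. Groups seen by fewer than 2 cameras are skipped.
#' @export
triangulate_keypoints <- function(table, cameras, refine = FALSE) {
  table <- tibble::as_tibble(table)
  table <- table[!is.na(table$x) & !is.na(table$y), ]
  keys <- dplyr::distinct(table[, c("frame", "node")])
  out <- purrr::map(seq_len(nrow(keys)), function(i) {
    obs <- table[table$frame == keys$frame[i] & table$node == keys$node[i], ]
    if (nrow(obs) < 2L) return(NULL)
    tp <- triangulate(obs[, c("camera", "x", "y")], cameras, refine = refine)
    tibble::tibble(
      frame = keys$frame[i], node = keys$node[i],
      X = tp$position[1], Y = tp$position[2], Z = tp$position[3],
      n_views = tp$n_views, degenerate = tp$degenerate,
      mean_reproj_px = mean(tp$per_view$reproj_px),
      mean_distance_mm = mean(tp$per_view$distance_mm),
      mean_angle_deg = mean(tp$per_view$angle_deg)
    )
  })
  bind_rows(out)
}
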