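# 8-connected component labeling (two-pass union-find). No installed package
# labels with 8-connectivity, and crops here are at most (2r+1)^2 pixels.
label_components <- function(binary) {
  stopifnot(is.matrix(binary))
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(w)) {
    for (rr in seq_len(h)) {
      if (!binary[rr, cc]) next
      neigh <- integer(0)
      if (rr > 1L && binary[rr - 1L, cc]) neigh <- c(neigh, lab[rr - 1L, cc])
      if (cc > 1L) {
        if (binary[rr, cc - 1L]) neigh <- c(neigh, lab[rr, cc - 1L])
        if (rr > 1L && binary[rr - 1L, cc - 1L]) neigh <- c(neigh, lab[rr - 1L, cc - 1L])
        if (rr < h && binary[rr + 1L, cc - 1L]) neigh <- c(neigh, lab[rr + 1L, cc - 1L])
      }
      if (length(neigh) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[rr, cc] <- nxt
      } else {
        roots <- unique(vapply(neigh, find, integer(1)))
        keep <- min(roots)
        lab[rr, cc] <- keep
        for (r2 in roots) parent[r2] <- keep
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

#' Select the fluorescent component nearest a point
#'
#' Thresholds a frame (or crop), labels the supra-threshold pixels with
#' 8-connectivity, and keeps only the connected component whose centroid is
#' nearest (L2) to the query point, zeroing all other pixels. Ties in centroid
#' distance are broken by larger integrated intensity, then by lower component
#' label, so selection is deterministic.
#'
#' @param frame Numeric matrix.
#' @param point Query point `c(x, y)`, 0-based pixel coordinates.
#' @param threshold Intensity threshold (pixels strictly above are foreground).
#' @param radius Optional L2 radius (px) around `point`; pixels outside the
#'   disk are ignored.
#' @return List with `mask` (logical matrix, the selected component), `empty`
#'   (TRUE when no supra-threshold pixel exists), `centroid` (`c(x, y)` or
#'   `NULL`), `peak` (max intensity on the component, or `NA`).
#' @export
select_nearest_component <- function(frame, point, threshold, radius = NULL) {
  stopifnot(is.matrix(frame), length(point) == 2L)
  if (threshold < 0) abort("`threshold` must be >= 0.")
  binary <- frame > threshold
  if (!is.null(radius)) {
    xs <- matrix(rep(.index_to_px(seq_len(ncol(frame))), each = nrow(frame)), nrow(frame))
    ys <- matrix(rep(.index_to_px(seq_len(nrow(frame))), ncol(frame)), nrow(frame))
    binary <- binary & ((xs - point[1])^2 + (ys - point[2])^2 <= radius^2)
  }
  if (!any(binary)) {
    return(list(mask = binary, empty = TRUE, centroid = NULL, peak = NA_real_))
  }
  lab <- label_components(binary)
  nlab <- max(lab)
  best <- 0L; best_d <- Inf; best_mass <- -Inf
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    cx <- mean(.index_to_px(idx[, 2])); cy <- mean(.index_to_px(idx[, 1]))
    d <- sqrt((cx - point[1])^2 + (cy - point[2])^2)
    mass <- sum(frame[lab == l])
    if (d < best_d - 1e-12 ||
        (abs(d - best_d) <= 1e-12 && mass > best_mass)) {
      best <- l; best_d <- d; best_mass <- mass
    }
  }
  mask <- lab == best
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(.index_to_px(idx[, 2])), mean(.index_to_px(idx[, 1])))
  list(mask = mask, empty = FALSE, centroid = centroid,
       peak = max(frame[mask]))
}

# shared axis-aligned bivariate Gaussian least-squares fit.
# z: numeric matrix; mask: optional logical matrix of pixels to fit.
# Coordinates are 0-based local pixel positions.
.fit_gauss2d <- function(z, mask = NULL) {
  h <- nrow(z); w <- ncol(z)
  xs <- rep(.index_to_px(seq_len(w)), each = h)
  ys <- rep(.index_to_px(seq_len(h)), w)
  vals <- as.vector(z)
  if (!is.null(mask)) {
    keep <- as.vector(mask)
    xs <- xs[keep]; ys <- ys[keep]; vals <- vals[keep]
  }
  out <- list(amplitude = NA_real_, cx = NA_real_, cy = NA_real_,
              sigma_x = NA_real_, sigma_y = NA_real_, offset = NA_real_,
              converged = FALSE, degenerate = FALSE, residual = NA_real_)
  if (length(vals) < 6L) return(out)
  rng <- diff(range(vals))
  if (rng <= .Machine$double.eps * max(abs(vals), 1)) {
    out$degenerate <- TRUE
    return(out)
  }
  off0 <- min(vals)
  wts <- pmax(vals - off0, 0)
  if (sum(wts) <= 0) { out$degenerate <- TRUE; return(out) }
  peak <- which.max(vals)
  cx0 <- xs[peak]; cy0 <- ys[peak]
  # width from the supra-half-maximum area (robust to a noise floor, unlike
  # raw second moments): n_half ~ pi * (FWHM/2)^2 for a 2-D Gaussian
  n_half <- sum(vals - off0 > (max(vals) - off0) / 2)
  s_half <- max(sqrt(n_half / pi) / 1.1774, 0.6)
  df <- data.frame(x = xs, y = ys, v = vals)
  fit <- NULL
  for (s0 in unique(c(s_half, 1.5, 3, max(w, h) / 6))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ off + amp * exp(-((x - cx)^2 / (2 * sx^2) + (y - cy)^2 / (2 * sy^2))),
        data = df,
        start = list(off = off0, amp = max(vals) - off0, cx = cx0, cy = cy0,
                     sx = s0, sy = s0),
        lower = c(-Inf, 0, min(xs) - 2, min(ys) - 2, 1e-3, 1e-3),
        upper = c(Inf, Inf, max(xs) + 2, max(ys) + 2, max(w, h) * 4, max(w, h) * 4),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(out)
  p <- coef(fit)
  out$amplitude <- unname(p["amp"]); out$offset <- unname(p["off"])
  out$cx <- unname(p["cx"]); out$cy <- unname(p["cy"])
  out$sigma_x <- unname(p["sx"]); out$sigma_y <- unname(p["sy"])
  out$residual <- sqrt(mean(resid(fit)^2))
  out$converged <- is.finite(out$cx) && is.finite(out$cy) &&
    out$sigma_x > 0 && out$sigma_y > 0
  out
}

#' Fit a bivariate Gaussian to a masked fluorescence crop
#'
#' Least-squares fit of an axis-aligned bivariate Gaussian plus constant
#' offset; the fitted center is the sub-pixel estimate of the fluorescence
#' center. At least 6 pixels of support are required for the 6 parameters to
#' be identifiable.
#'
#' @param crop Numeric matrix (local coordinates, 0-based).
#' @param mask Optional logical matrix: pixels to fit (e.g. the selected
#'   component). Default: all pixels.
#' @return A `qdpi_spotfit` object with fields `cx`, `cy`, `sigma_x`,
#'   `sigma_y`, `amplitude`, `offset`, `converged`, `degenerate`, `residual`.
#' @export
fit_spot <- function(crop, mask = NULL) {
  fit <- .fit_gauss2d(crop, mask)
  structure(fit, class = "qdpi_spotfit")
}

#' @export
print.qdpi_spotfit <- function(x, ...) {
  if (!x$converged) {
    cat("<qdpi_spotfit> not converged",
        if (x$degenerate) " (degenerate support)", "\n", sep = "")
  } else {
    cat(sprintf(
      "<qdpi_spotfit> center (%.3f, %.3f) px, sigma (%.3f, %.3f) px, amp %.2f, offset %.2f\n",
      x$cx, x$cy, x$sigma_x, x$sigma_y, x$amplitude, x$offset))
  }
  invisible(x)
}

#' @export
tidy.qdpi_spotfit <- function(x, ...) {
  tibble::tibble(
    term = c("cx", "cy", "sigma_x", "sigma_y", "amplitude", "offset"),
    estimate = c(x$cx, x$cy, x$sigma_x, x$sigma_y, x$amplitude, x$offset)
  )
}

#' @export
glance.qdpi_spotfit <- function(x, ...) {
  tibble::tibble(converged = x$converged, degenerate = x$degenerate,
                 residual = x$residual)
}

#' Intensity-weighted center of mass of a crop
#'
#' @param crop Numeric matrix.
#' @param mask Optional logical matrix restricting the computation.
#' @return `c(x, y)`, 0-based pixel coordinates.
#' @export
center_of_mass <- function(crop, mask = NULL) {
  stopifnot(is.matrix(crop))
  h <- nrow(crop); w <- ncol(crop)
  xs <- rep(.index_to_px(seq_len(w)), each = h)
  ys <- rep(.index_to_px(seq_len(h)), w)
  vals <- as.vector(crop)
  if (!is.null(mask)) {
    keep <- as.vector(mask)
    xs <- xs[keep]; ys <- ys[keep]; vals <- vals[keep]
  }
  tot <- sum(vals)
  if (!is.finite(tot) || tot <= 0) abort("zero total intensity; center of mass undefined.")
  c(x = sum(vals * xs) / tot, y = sum(vals * ys) / tot)
}

#' Refine keypoint predictions to fluorescence centers
#'
#' For every predicted keypoint, the fluorescence center within `radius`
#' pixels replaces the prediction: the crop around the prediction is
#' thresholded (Otsu within the crop, with an absolute floor), the connected
#' component nearest the prediction is selected, and its center is estimated
#' by bivariate Gaussian fit (falling back to center of mass when the fit
#' fails) or directly by center of mass. Keypoints with no supra-threshold
#' fluorescence in the search disk are left unrefined and flagged.
#'
#' @param table Keypoint table (see [keypoint_table()]); `frame` indexes the
#'   fluorescence stack (0-based).
#' @param fluorescence 3-D array (frame, row, col), background-subtracted.
#' @param radius Search radius in pixels (default 10).
#' @param method `"gaussian_fit"` (default) or `"center_of_mass"`.
#' @param threshold_floor Absolute intensity floor for the crop threshold
#'   (default 10 a.u.), suppressing noise-only crops.
#' @return The input tibble with columns `refined_x`, `refined_y`,
#'   `distance_moved`, `peak_value`, `refined` (logical), `refine_method`.
#' @export
refine_keypoints <- function(table, fluorescence, radius = 10,
                             method = c("gaussian_fit", "center_of_mass"),
                             threshold_floor = 10) {
  method <- match.arg(method)
  table <- keypoint_table(table)
  stopifnot(is.array(fluorescence), length(dim(fluorescence)) == 3L)
  n_fr <- dim(fluorescence)[1]
  h <- dim(fluorescence)[2]; w <- dim(fluorescence)[3]
  n <- nrow(table)
  rx <- ry <- dm <- pk <- rep(NA_real_, n)
  refined <- rep(FALSE, n)
  used <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    x0 <- table$x[i]; y0 <- table$y[i]
    fi <- table$frame[i]
    if (is.na(x0) || is.na(y0) || fi < 0 || fi >= n_fr) next
    fr <- fluorescence[.px_to_index(fi), , ]
    # square crop of half-width radius, clipped at frame borders
    r0 <- max(1L, .px_to_index(round(y0)) - radius)
    r1 <- min(h, .px_to_index(round(y0)) + radius)
    c0 <- max(1L, .px_to_index(round(x0)) - radius)
    c1 <- min(w, .px_to_index(round(x0)) + radius)
    crop <- fr[r0:r1, c0:c1, drop = FALSE]
    local_pt <- c(x0 - .index_to_px(c0), y0 - .index_to_px(r0))
    thr <- max(.crop_threshold(crop), threshold_floor)
    sel <- select_nearest_component(crop, local_pt, thr, radius = radius)
    if (sel$empty) next
    center <- NULL
    used_i <- method
    if (method == "gaussian_fit") {
      fit <- .fit_gauss2d(crop, sel$mask)
      if (fit$converged) center <- c(fit$cx, fit$cy)
    }
    if (is.null(center)) {
      center <- unname(center_of_mass(crop, sel$mask))
      used_i <- "center_of_mass"
    }
    d <- sqrt((center[1] - local_pt[1])^2 + (center[2] - local_pt[2])^2)
    if (d > radius) {  # fitted center wandered outside the search disk
      center <- unname(center_of_mass(crop, sel$mask))
      used_i <- "center_of_mass"
      d <- sqrt((center[1] - local_pt[1])^2 + (center[2] - local_pt[2])^2)
    }
    rx[i] <- center[1] + .index_to_px(c0)
    ry[i] <- center[2] + .index_to_px(r0)
    dm[i] <- d
    pk[i] <- sel$peak
    refined[i] <- TRUE
    used[i] <- used_i
  }
  table$refined_x <- rx
  table$refined_y <- ry
  table$distance_moved <- dm
  table$peak_value <- pk
  table$refined <- refined
  table$refine_method <- used
  table
}

# Otsu threshold of a crop, falling back to 0 for (near-)constant crops
.crop_threshold <- function(crop) {
  if (diff(range(crop)) <= 0) return(0)
  tryCatch(otsu_threshold(crop), error = function(e) 0)
}
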