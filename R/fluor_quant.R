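#' Rolling background subtraction
#'
#' Removes the static background from a fluorescence stack by estimating a
#' per-pixel background over nonoverlapping blocks of `window` frames
#' (default 1500) and subtracting it from every frame in the block. A short
#' final block uses its own frames. Negative residuals are clamped to zero,
#' since intensities are non-negative.
#'
#' @param stack 3-D numeric array (frame, row, col).
#' @param window Block length in frames.
#' @param stat Per-pixel block statistic: `"median"` (default, robust to
#'   transient bright spots), `"mean"` or `"min"`.
#' @return Background-subtracted stack, same shape.
#' @export
subtract_rolling_background <- function(stack, window = 1500L,
                                        stat = c("median", "mean", "min")) {
  stat <- match.arg(stat)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  n <- dim(stack)[1]
  if (n == 0L) abort("empty stack.")
  if (window < 1L) abort("`window` must be >= 1.")
  statfun <- switch(stat, median = stats::median, mean = mean, min = min)
  out <- stack
  starts <- seq(1L, n, by = window)
  for (s in starts) {
    idx <- s:min(s + window - 1L, n)
    block <- stack[idx, , , drop = FALSE]
    bg <- apply(block, c(2, 3), statfun)
    for (i in idx) out[i, , ] <- stack[i, , ] - bg
  }
  out[out < 0] <- 0
  out
}

#' Per-frame maximum intensity trace
#'
#' The paper-standard per-frame summary: the maximum pixel value of each
#' fluorescence frame, optionally restricted to a subject mask so that pixels
#' off the animal are ignored.
#'
#' @param stack 3-D numeric array (frame, row, col), normally
#'   background-subtracted.
#' @param mask Optional mask: a logical/0-1 matrix applied to every frame, or a
#'   3-D array of per-frame masks. A frame whose mask is empty yields `NA`
#'   (with a warning).
#' @return A tibble with columns `frame` (0-based) and `value`.
#' @export
frame_max_trace <- function(stack, mask = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  n <- dim(stack)[1]
  vals <- numeric(n)
  per_frame_mask <- !is.null(mask) && length(dim(mask)) == 3L
  if (!is.null(mask) && !per_frame_mask &&
      !identical(dim(mask), dim(stack)[2:3])) {
    abort("mask shape must match frame shape.")
  }
  n_empty <- 0L
  for (i in seq_len(n)) {
    fr <- stack[i, , ]
    m <- if (is.null(mask)) NULL else if (per_frame_mask) mask[i, , ] else mask
    if (is.null(m)) {
      vals[i] <- max(fr)
    } else if (!any(m > 0)) {
      vals[i] <- NA_real_
      n_empty <- n_empty + 1L
    } else {
      vals[i] <- max(fr[m > 0])
    }
  }
  if (n_empty > 0L) warn(sprintf("%d frame(s) had an empty mask; values set to NA.", n_empty))
  tibble::tibble(frame = .index_to_px(seq_len(n)), value = vals)
}

#' Summarise a per-frame intensity trace for one session
#'
#' Reduces a per-frame trace to the two session-level scalars used throughout:
#' the mean and the 95th percentile (linear interpolation) of the per-frame
#' values.
#'
#' @param trace A tibble with a `value` column (see [frame_max_trace()]), or a
#'   numeric vector.
#' @return A one-row tibble with `n_frames`, `mean_value`, `p95_value`.
#' @export
summarize_session <- function(trace) {
  vals <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) abort("empty trace.")
  tibble::tibble(
    n_frames = length(vals),
    mean_value = mean(vals),
    p95_value = unname(quantile(vals, 0.95, type = 7))
  )
}

#' Signal-to-noise as a ratio of session means
#'
#' SNR of marker-injected sessions relative to vehicle/blank controls:
#' the mean of the marker sessions' summary values divided by the mean of the
#' control sessions' summary values.
#'
#' @param qd_summaries,control_summaries Data frames with the summary column,
#'   one row per session, or numeric vectors.
#' @param value Name of the summary column (default `"mean_value"`).
#' @return A single ratio.
#' @export
snr_mean_ratio <- function(qd_summaries, control_summaries, value = "mean_value") {
  grab <- function(x) if (is.data.frame(x)) x[[value]] else as.numeric(x)
  q <- grab(qd_summaries); ctrl <- grab(control_summaries)
  if (length(q) < 1L || length(ctrl) < 1L) abort("need at least one session per group.")
  denom <- mean(ctrl)
  if (!is.finite(denom) || denom <= 0) abort("control mean must be positive.")
  mean(q) / denom
}

#' Signal-to-noise as mean spatial standard deviation
#'
#' For each fluorescence frame, the standard deviation of all pixel values
#' (population form, i.e. divisor `n`), averaged over frames. A bright
#' localized marker inflates the spatial SD relative to blank frames, so this
#' acts as a per-recording SNR score when referenced to control animals.
#'
#' @param stack 3-D numeric array (frame, row, col).
#' @param marginal If `TRUE`, use the mean of the SDs of the row- and
#'   column-marginal profiles instead of the all-pixel SD.
#' @return Scalar.
#' @export
snr_spatial_sd <- function(stack, marginal = FALSE) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  n <- dim(stack)[1]
  if (n == 0L) abort("empty stack.")
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  per_frame <- vapply(seq_len(n), function(i) {
    fr <- stack[i, , ]
    if (marginal) {
      mean(c(sd_pop(rowMeans(fr)), sd_pop(colMeans(fr))))
    } else {
      sd_pop(as.vector(fr))
    }
  }, numeric(1))
  mean(per_frame)
}

#' Fluorescence longevity of one mouse/camera pair
#'
#' Longevity is the first post-injection day on which the session summary
#' falls below the control threshold — the 99th percentile of the per-frame
#' maximum values pooled across all vehicle/blank control sessions. A trace
#' that never crosses is censored at its last imaged day.
#'
#' @param summaries Tibble with columns `day` and `value` (one session summary
#'   per imaging day), sorted or sortable by day.
#' @param control_values Numeric vector of pooled per-frame maximum values
#'   from all control sessions.
#' @param prob Control percentile defining the threshold (default 0.99).
#' @return One-row tibble: `control_threshold`, `crossing_day` (`NA` when
#'   censored), `censored`, `last_day`.
#' @export
longevity <- function(summaries, control_values, prob = 0.99) {
  if (length(control_values) == 0L) abort("no control data.")
  summaries <- dplyr::arrange(tibble::as_tibble(summaries), .data$day)
  thr <- unname(quantile(control_values, prob, type = 7))
  below <- which(summaries$value < thr)
  tibble::tibble(
    control_threshold = thr,
    crossing_day = if (length(below)) summaries$day[below[1]] else NA_real_,
    censored = length(below) == 0L,
    last_day = max(summaries$day)
  )
}

#' Spatial autocorrelation map of a fluorescence stack
#'
#' Computes the full 2-D autocorrelation (correlation of each frame with
#' itself at every lag) on a subsample of frames (every `stride`-th frame),
#' normalizes each frame's map to 1 at zero lag, and averages the maps. The
#' width of the resulting peak measures the spatial spread of marker
#' fluorescence. All-zero frames have undefined normalization and are skipped
#' with a warning.
#'
#' @param stack Background-subtracted 3-D array (frame, row, col).
#' @param stride Frame subsampling stride (default 200).
#' @return A `qdpi_autocorr` object: list with `map` ((2H-1) x (2W-1) matrix,
#'   centered at zero lag), `n_frames_used`, `n_skipped`.
#' @export
spatial_autocorrelation <- function(stack, stride = 200L) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (stride < 1L) abort("`stride` must be >= 1.")
  n <- dim(stack)[1]
  h <- dim(stack)[2]; w <- dim(stack)[3]
  idx <- seq(1L, n, by = stride)
  acc <- matrix(0, 2L * h - 1L, 2L * w - 1L)
  used <- 0L
  for (i in idx) {
    fr <- stack[i, , ]
    if (all(fr == 0)) next
    m <- .xcorr2_full(fr, fr)
    acc <- acc + m / m[h, w]  # zero lag sits at (h, w)
    used <- used + 1L
  }
  if (used == 0L) abort("all sampled frames are zero; autocorrelation undefined.")
  if (used < length(idx)) {
    warn(sprintf("skipped %d all-zero frame(s).", length(idx) - used))
  }
  structure(
    list(map = acc / used, n_frames_used = used,
         n_skipped = length(idx) - used),
    class = "qdpi_autocorr"
  )
}

# full 2-D cross-correlation via FFT; output size (2h-1) x (2w-1),
# zero lag at (h, w)
.xcorr2_full <- function(a, b) {
  h <- nrow(a); w <- ncol(a)
  H <- 2L * h - 1L; W <- 2L * w - 1L
  pa <- matrix(0, H, W); pa[1:h, 1:w] <- a
  pb <- matrix(0, H, W); pb[1:h, 1:w] <- b
  cc <- Re(fft(fft(pa) * Conj(fft(pb)), inverse = TRUE)) / (H * W)
  # circular correlation -> linear lags: shift so lag 0 is centered
  ord_r <- c((h + 1L):H, 1:h)
  ord_c <- c((w + 1L):W, 1:w)
  cc[ord_r, ord_c]
}

#' @export
print.qdpi_autocorr <- function(x, ...) {
  cat("<qdpi_autocorr> map ", nrow(x$map), "x", ncol(x$map), ", averaged over ",
      x$n_frames_used, " frame(s)\n", sep = "")
  invisible(x)
}

#' Estimate fluorescence spread from an autocorrelation map
#'
#' Fits a bivariate (axis-aligned) Gaussian to the autocorrelation surface by
#' least squares; the fitted standard deviations along x and y are the spread
#' estimates. For a single Gaussian spot of width sigma the autocorrelation is
#' a Gaussian of width sigma * sqrt(2).
#'
#' @param map A `qdpi_autocorr` or a numeric matrix centered at zero lag.
#' @return One-row tibble: `spread_x`, `spread_y` (pixels), `amplitude`,
#'   `offset`, `converged`, `degenerate`.
#' @export
estimate_spread <- function(map) {
  m <- if (inherits(map, "qdpi_autocorr")) map$map else map
  stopifnot(is.matrix(m))
  fit <- .fit_gauss2d(m)
  tibble::tibble(
    spread_x = fit$sigma_x, spread_y = fit$sigma_y,
    amplitude = fit$amplitude, offset = fit$offset,
    converged = fit$converged, degenerate = fit$degenerate
  )
}

#' @describeIn estimate_spread Heatmap of the central region of the map.
#' @param object,x A `qdpi_autocorr`.
#' @param half_width Lags to display on each side of zero.
#' @param ... Unused.
#' @export
autoplot.qdpi_autocorr <- function(object, half_width = 30L, ...) {
  m <- object$map
  c_r <- (nrow(m) + 1L) %/% 2L; c_c <- (ncol(m) + 1L) %/% 2L
  rows <- max(1L, c_r - half_width):min(nrow(m), c_r + half_width)
  cols <- max(1L, c_c - half_width):min(ncol(m), c_c + half_width)
  df <- expand.grid(dy = rows - c_r, dx = cols - c_c)
  df$value <- as.vector(m[rows, cols])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dx, y = .data$dy, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "corr") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lag x (px)", y = "lag y (px)",
                  title = "Spatial autocorrelation")
}

#' @export
plot.qdpi_autocorr <- function(x, ...) print(autoplot(x, ...))
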