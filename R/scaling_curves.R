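#' Evaluate a sample-efficiency power law
#'
#' Two forms link training-set size `x` (frames) to a performance metric `y`:
#' the decay form `y = a * (x + 1)^b + c` (error falling with more training
#' data; `a > 0`, `b < 0`) and the saturating form
#' `y = a * (1 - 1 / (x + 1)^b) + c`.
#'
#' @param x Training frame counts (>= 0).
#' @param a,b,c Coefficients.
#' @param form `"decay"` or `"saturating"`.
#' @return Numeric vector of metric values.
#' @export
power_law <- function(x, a, b, c, form = c("decay", "saturating")) {
  form <- match.arg(form)
  if (form == "decay") a * (x + 1)^b + c else a * (1 - 1 / (x + 1)^b) + c
}

#' Fit a power-law sample-efficiency curve
#'
#' Least-squares fit of the decay or saturating power law to
#' (frame count, metric) points, with multi-start initialization over the
#' exponent: the starts jitter `b0 = -0.5` (decay) or `+0.5` (saturating) by
#' factors 1/4 to 4, plus a swapped-offset start, and the best residual sum
#' of squares wins. Constant-metric data leave the exponent unidentifiable
#' and are flagged degenerate.
#'
#' @param points Data frame with columns `x` (frames) and `y` (metric), or
#'   columns `n_frames` and `error_px`.
#' @param form `"decay"` or `"saturating"`.
#' @return A `qdpi_powerlaw` object: fields `a`, `b`, `c`, `form`,
#'   `converged`, `degenerate`, `rss`, `points`.
#' @export
fit_power_law <- function(points, form = c("decay", "saturating")) {
  form <- match.arg(form)
  points <- .as_xy(points)
  if (nrow(points) < 4L) abort("need at least 4 points to fit a 3-parameter curve.")
  if (any(points$x < 0)) abort("frame counts must be >= 0.")
  out <- structure(
    list(a = NA_real_, b = NA_real_, c = NA_real_, form = form,
         converged = FALSE, degenerate = FALSE, rss = NA_real_,
         points = points),
    class = "qdpi_powerlaw"
  )
  if (diff(range(points$y)) <= .Machine$double.eps * max(abs(points$y), 1)) {
    out$degenerate <- TRUE
    return(out)
  }
  c0 <- if (form == "decay") min(points$y) else max(points$y)
  a0 <- points$y[which.min(points$x)] - c0
  if (abs(a0) < 1e-8) a0 <- diff(range(points$y)) * sign(a0 + 1e-12)
  b0 <- if (form == "decay") -0.5 else 0.5
  starts <- c(lapply(c(1, 0.25, 0.5, 2, 4), function(f) list(a = a0, b = b0 * f, c = c0)),
              list(list(a = -a0, b = b0,
                        c = if (form == "decay") max(points$y) else min(points$y))))
  fn <- if (form == "decay") {
    y ~ a * (x + 1)^b + c
  } else {
    y ~ a * (1 - 1 / (x + 1)^b) + c
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(fn, data = points, start = s,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(out)
  p <- coef(best$fit)
  out$a <- unname(p["a"]); out$b <- unname(p["b"]); out$c <- unname(p["c"])
  out$rss <- best$rss
  out$converged <- all(is.finite(p))
  out
}

.as_xy <- function(points) {
  points <- tibble::as_tibble(points)
  if (!all(c("x", "y") %in% names(points))) {
    if (all(c("n_frames", "error_px") %in% names(points))) {
      points <- dplyr::rename(points, x = "n_frames", y = "error_px")
    } else {
      abort("`points` must have columns (x, y) or (n_frames, error_px).")
    }
  }
  points[, c("x", "y")]
}

#' @export
print.qdpi_powerlaw <- function(x, ...) {
  if (x$degenerate) {
    cat("<qdpi_powerlaw> degenerate (constant metric; exponent unidentifiable)\n")
  } else {
    cat(sprintf("<qdpi_powerlaw> %s: a = %.4g, b = %.4g, c = %.4g (rss %.3g, n = %d)\n",
                x$form, x$a, x$b, x$c, x$rss, nrow(x$points)))
  }
  invisible(x)
}

#' @export
tidy.qdpi_powerlaw <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @export
glance.qdpi_powerlaw <- function(x, ...) {
  tibble::tibble(form = x$form, rss = x$rss, n = nrow(x$points),
                 converged = x$converged, degenerate = x$degenerate)
}

#' @export
predict.qdpi_powerlaw <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$points$x else
    if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  power_law(x, object$a, object$b, object$c, object$form)
}

#' Case-resampling bootstrap band for a power-law fit
#'
#' Resamples (frame count, metric) pairs with replacement, refits the curve
#' (initialized at the full-data estimate), and reports per-x 2.5% / 97.5%
#' percentiles plus the median fitted curve. Resamples whose frame counts are
#' all identical cannot identify the exponent and are discarded (counted in
#' `n_degenerate`).
#'
#' @param points As in [fit_power_law()].
#' @param form `"decay"` or `"saturating"`.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; fixed seed gives a bit-identical band.
#' @param x_grid Frame counts at which to evaluate the band; defaults to 50
#'   points spanning the observed range.
#' @return A `qdpi_powerlaw_band`: tibble with `x`, `low`, `median`, `high`;
#'   attributes `fit` (full-data `qdpi_powerlaw`), `n_boot`, `n_degenerate`.
#' @export
bootstrap_band <- function(points, form = c("decay", "saturating"),
                           n_boot = 1000L, seed = NULL, x_grid = NULL) {
  form <- match.arg(form)
  if (n_boot < 100L) abort("`n_boot` must be >= 100.")
  points <- .as_xy(points)
  full <- fit_power_law(points, form)
  if (!full$converged) abort("full-data fit did not converge; no band computed.")
  if (is.null(x_grid)) {
    x_grid <- seq(min(points$x), max(points$x), length.out = 50)
  }
  if (!is.null(seed)) set.seed(seed)
  fn <- if (form == "decay") y ~ a * (x + 1)^b + c else y ~ a * (1 - 1 / (x + 1)^b) + c
  start <- list(a = full$a, b = full$b, c = full$c)
  curves <- matrix(NA_real_, n_boot, length(x_grid))
  n_degenerate <- 0L
  for (i in seq_len(n_boot)) {
    idx <- sample.int(nrow(points), replace = TRUE)
    bs <- points[idx, ]
    if (length(unique(bs$x)) < 2L) { n_degenerate <- n_degenerate + 1L; next }
    fit <- tryCatch(
      minpack.lm::nlsLM(fn, data = bs, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) { n_degenerate <- n_degenerate + 1L; next }
    p <- coef(fit)
    curves[i, ] <- power_law(x_grid, p["a"], p["b"], p["c"], form)
  }
  ok <- stats::complete.cases(curves)
  if (!any(ok)) abort("no bootstrap resample produced a fit.")
  band <- tibble::tibble(
    x = x_grid,
    low = apply(curves[ok, , drop = FALSE], 2, quantile, 0.025, type = 7),
    median = apply(curves[ok, , drop = FALSE], 2, median),
    high = apply(curves[ok, , drop = FALSE], 2, quantile, 0.975, type = 7)
  )
  attr(band, "fit") <- full
  attr(band, "n_boot") <- n_boot
  attr(band, "n_degenerate") <- n_degenerate
  class(band) <- c("qdpi_powerlaw_band", class(band))
  band
}

#' Training frames required to reach an error threshold
#'
#' Inverts a fitted decay power law: `x = (a / (t - c))^(-1/b) - 1`, rounded
#' up to the next integer so the threshold is guaranteed to be met. When the
#' threshold lies at or below the asymptote `c`, no finite training set
#' reaches it and `Inf` is returned.
#'
#' @param fit A converged decay-form `qdpi_powerlaw` with `a > 0`, `b < 0`.
#' @param error_threshold Target error (same units as the fitted metric).
#' @return Integer frame count, or `Inf` when unreachable.
#' @examples
#' pts <- data.frame(x = c(0, 10, 100, 1000), y = 10 * (c(0, 10, 100, 1000) + 1)^-0.5 + 1)
#' frames_required(fit_power_law(pts), 2)
#' @export
frames_required <- function(fit, error_threshold) {
  stopifnot(inherits(fit, "qdpi_powerlaw"))
  if (fit$form != "decay") abort("frames_required needs a decay-form fit.")
  if (!fit$converged) abort("fit did not converge.")
  if (!(fit$a > 0 && fit$b < 0)) {
    abort("inversion requires a > 0 and b < 0 (monotone decreasing error).")
  }
  vapply(error_threshold, function(t) {
    if (t <= fit$c) return(Inf)
    ceiling((fit$a / (t - fit$c))^(1 / (-fit$b)) - 1)
  }, numeric(1))
}

#' @describeIn fit_power_law Points, fitted curve and optional bootstrap band.
#' @param object A `qdpi_powerlaw`.
#' @param band Optional `qdpi_powerlaw_band` to shade.
#' @param ... Unused.
#' @export
autoplot.qdpi_powerlaw <- function(object, band = NULL, ...) {
  grid <- tibble::tibble(x = seq(min(object$points$x), max(object$points$x),
                                 length.out = 200))
  grid$y <- predict(object, grid)
  p <- ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(band)) {
    p <- p + ggplot2::geom_ribbon(
      data = band, ggplot2::aes(x = .data$x, ymin = .data$low, ymax = .data$high),
      inherit.aes = FALSE, alpha = 0.25)
  }
  p +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::labs(x = "training frames", y = "error (px)",
                  title = sprintf("Power-law %s fit", object$form))
}

#' @export
plot.qdpi_powerlaw <- function(x, ...) print(autoplot(x, ...))
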