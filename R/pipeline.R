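#' Run the full synthetic analysis pipeline end to end
#'
#' One seeded configuration drives the whole chain: simulate a multiplexed
#' recording, demultiplex it, subtract the rolling background, quantify
#' per-frame and per-session fluorescence, estimate spatial spread, simulate
#' tracker keypoints from the ground truth, refine them to fluorescence
#' centers, run the quality-control cascade, and fit a sample-efficiency
#' power law (on generator-produced error-vs-frames points) with
#' frames-required thresholds. All randomness derives from `seed`, so two
#' runs with the same seed are identical.
#'
#' @param seed Integer seed.
#' @param config A [sim_config()]; its seed is replaced by `seed`.
#' @param error_thresholds_px Error thresholds (px) at which to invert the
#'   fitted decay curve; defaults to the 2 mm and 1 mm equivalents of the
#'   standard optics (4.9 and 2.45 px).
#' @return A list with elements `summary` (one-row tibble of headline
#'   numbers), `session`, `spread`, `refined`, `qc`, `scaling_fit`,
#'   `frames_required`.
#' @export
run_pipeline <- function(seed = 1L, config = NULL,
                         error_thresholds_px = c(4.9, 2.45)) {
  if (is.null(config)) config <- sim_config(seed = seed)
  config$seed <- as.integer(seed)

  sim <- simulate_recording(config)
  demux <- demultiplex(sim$recording)
  fluor <- subtract_rolling_background(demux$fluorescence, window = 1500)
  trace <- frame_max_trace(fluor)
  session <- summarize_session(trace)
  spatial_snr <- snr_spatial_sd(fluor)
  ac <- spatial_autocorrelation(fluor, stride = 5)
  spread <- estimate_spread(ac)

  kp <- simulate_keypoints(sim$truth$spots, config)
  refined <- refine_keypoints(kp$keypoints, fluor, radius = 10)
  qc_in <- refined
  qc_in$center_dist <- refined$distance_moved
  qc <- run_cascade(qc_in, qc_config(pca_enabled = FALSE))

  # generator-produced sample-efficiency points: error falls as a power law
  # of the training-set size, with multiplicative noise
  pts <- withr::with_seed(config$seed + 4L, {
    x <- round(10^seq(log10(10), log10(5000), length.out = 24))
    tibble::tibble(x = x,
                   y = power_law(x, a = 30, b = -0.45, c = 1.5, "decay") *
                     exp(rnorm(length(x), 0, 0.05)))
  })
  fit <- fit_power_law(pts, "decay")
  req <- frames_required(fit, error_thresholds_px)

  list(
    summary = tibble::tibble(
      n_frames = dim(sim$recording$frames)[1],
      mean_value = session$mean_value,
      p95_value = session$p95_value,
      spatial_snr = spatial_snr,
      spread_x = spread$spread_x,
      spread_y = spread$spread_y,
      median_refined_error = median(
        sqrt((refined$refined_x - sim$truth$spots$cx)^2 +
               (refined$refined_y - sim$truth$spots$cy)^2), na.rm = TRUE),
      n_surviving = nrow(qc$surviving),
      fit_a = fit$a, fit_b = fit$b, fit_c = fit$c
    ),
    session = session, spread = spread, refined = refined, qc = qc,
    scaling_fit = fit,
    frames_required = tibble::tibble(threshold_px = error_thresholds_px,
                                     frames = req)
  )
}
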