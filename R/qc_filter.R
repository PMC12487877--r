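#' Quality-control configuration for the keypoint filter cascade
#'
#' Defaults follow the published cascade for the 10 standard body keypoints:
#' keypoints moving more than 30 px between neighboring frames are excluded; a
#' keypoint is visible when its confidence exceeds 0.2; among visible
#' keypoints, the minimum fluorescence peak scales linearly from 75 a.u. at
#' confidence 0.7 to 25 a.u. at 1.0 and the maximum distance to the nearest
#' fluorescence center from 5 px to 15 px; the allowed number of dropped
#' (visible but invalid) keypoints scales from 0 at 3 visible keypoints to 3
#' at 10; frames with any keypoint pair farther apart than 300 px are
#' excluded. The knee-joint variant anchors the confidence scaling at 0.5 and
#' skips the PCA stage (only two keypoints).
#'
#' @param knee Use the knee-joint variant.
#' @param ... Named overrides of any field below.
#' @return A `qdpi_qc_config` list with fields `max_jump`, `visibility_score`,
#'   `low_anchor_score`, `fluor_peak_at_low_anchor`, `fluor_peak_at_score1`,
#'   `max_dist_at_low_anchor`, `max_dist_at_score1`, `budget_min_keypoints`,
#'   `budget_max_keypoints`, `budget_max_drops`, `max_pair_distance`,
#'   `pca_mse_drop_fraction`, `pca_enabled`, `pca_outlier_mads`,
#'   `pca_min_error`.
#' @export
qc_config <- function(knee = FALSE, ...) {
  cfg <- list(
    max_jump = 30,
    visibility_score = 0.2,
    low_anchor_score = if (knee) 0.5 else 0.7,
    fluor_peak_at_low_anchor = 75,
    fluor_peak_at_score1 = 25,
    max_dist_at_low_anchor = 5,
    max_dist_at_score1 = 15,
    budget_min_keypoints = 3L,
    budget_max_keypoints = 10L,
    budget_max_drops = 3L,
    max_pair_distance = 300,
    pca_mse_drop_fraction = 0.90,
    pca_enabled = !knee,
    # frames are PCA outliers when reconstruction MSE exceeds
    # median + pca_outlier_mads * 1.4826 * MAD, and exceeds pca_min_error
    # (a numerical floor so machine-epsilon residuals are never outliers)
    pca_outlier_mads = 5,
    pca_min_error = 1e-6
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(paste0("unknown qc_config field(s): ", paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  if (cfg$low_anchor_score >= 1) abort("`low_anchor_score` must be < 1.")
  if (cfg$fluor_peak_at_low_anchor < cfg$fluor_peak_at_score1) {
    abort("fluorescence threshold must decrease with confidence.")
  }
  if (cfg$max_dist_at_low_anchor > cfg$max_dist_at_score1) {
    abort("distance threshold must increase with confidence.")
  }
  if (cfg$max_jump <= 0 || cfg$max_pair_distance <= 0) {
    abort("`max_jump` and `max_pair_distance` must be positive.")
  }
  structure(cfg, class = "qdpi_qc_config")
}

#' Confidence-scaled validity thresholds
#'
#' Less confident keypoints require brighter fluorescence evidence and must
#' lie closer to the nearest fluorescence center. Both thresholds are linear
#' in the confidence score between the low anchor (default 0.7) and 1.0;
#' scores below the anchor are clamped to the anchor's thresholds.
#'
#' @param score Confidence score(s) in \[0, 1\].
#' @param config A [qc_config()].
#' @return Tibble with columns `score`, `min_fluor_peak` (a.u.),
#'   `max_center_distance` (px).
#' @examples
#' validity_thresholds(c(0.7, 0.85, 1.0), qc_config())
#' @export
validity_thresholds <- function(score, config = qc_config()) {
  if (any(!is.na(score) & (score < 0 | score > 1))) abort("`score` must lie in [0, 1].")
  s <- pmax(pmin(score, 1), config$low_anchor_score)
  frac <- (s - config$low_anchor_score) / (1 - config$low_anchor_score)
  tibble::tibble(
    score = score,
    min_fluor_peak = config$fluor_peak_at_low_anchor +
      frac * (config$fluor_peak_at_score1 - config$fluor_peak_at_low_anchor),
    max_center_distance = config$max_dist_at_low_anchor +
      frac * (config$max_dist_at_score1 - config$max_dist_at_low_anchor)
  )
}

#' Allowed dropped-keypoint budget for a frame
#'
#' A frame whose number of dropped keypoints (visible minus valid) exceeds
#' this budget is excluded. The budget is 0 for frames with 3 or fewer
#' visible keypoints, 3 for frames with 10 or more, linear (floored to an
#' integer) in between.
#'
#' @param n_visible Number(s) of visible keypoints.
#' @param config A [qc_config()].
#' @return Integer vector of allowed drops.
#' @examples
#' drop_budget(c(3, 7, 10))
#' @export
drop_budget <- function(n_visible, config = qc_config()) {
  if (any(n_visible < 0)) abort("`n_visible` must be >= 0.")
  lo <- config$budget_min_keypoints
  hi <- config$budget_max_keypoints
  mx <- config$budget_max_drops
  frac <- pmin(pmax((n_visible - lo) / (hi - lo), 0), 1)
  as.integer(floor(mx * frac))
}

#' Flag implausible frame-to-frame jumps in keypoint tracks
#'
#' A keypoint is flagged when its L2 displacement from either neighboring
#' detection of the same node/camera track strictly exceeds `max_jump`.
#' First and last detections are compared only to their single neighbor.
#'
#' @param table Keypoint table with `frame`, `camera`, `node`, `x`, `y`.
#' @param max_jump Threshold in pixels (default from [qc_config()]).
#' @return Input tibble plus a logical `excluded_jump` column.
#' @export
jump_filter <- function(table, max_jump = qc_config()$max_jump) {
  table <- tibble::as_tibble(table)
  table %>%
    group_by(.data$camera, .data$node) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    mutate(
      .d_prev = sqrt((.data$x - lag(.data$x))^2 + (.data$y - lag(.data$y))^2),
      .d_next = sqrt((lead(.data$x) - .data$x)^2 + (lead(.data$y) - .data$y)^2),
      excluded_jump = (!is.na(.data$.d_prev) & .data$.d_prev > max_jump) |
        (!is.na(.data$.d_next) & .data$.d_next > max_jump)
    ) %>%
    ungroup() %>%
    select(-".d_prev", -".d_next")
}

#' PCA-based pose outlier detection
#'
#' Pose vectors (the x/y coordinates of all nodes in a frame) are decomposed
#' by principal components; the component count k is the smallest k whose
#' reconstruction reduces the cumulative mean squared reconstruction error by
#' at least `pca_mse_drop_fraction` (default 90%). Frames whose individual
#' reconstruction error exceeds `median + pca_outlier_mads * 1.4826 * MAD`
#' of the per-frame errors (and exceeds the numerical floor `pca_min_error`)
#' are flagged as outliers. Only frames with all nodes present enter the
#' decomposition; incomplete frames are not flagged.
#'
#' @param table Keypoint table (one camera at a time or grouped internally by
#'   camera).
#' @param config A [qc_config()].
#' @return Tibble with `camera`, `frame`, `recon_error`, `excluded_pca`;
#'   attribute `n_components` records k per camera. Returns zero rows (with a
#'   warning) when fewer than 2 complete frames exist.
#' @export
pca_outlier_filter <- function(table, config = qc_config()) {
  table <- tibble::as_tibble(table)
  nodes <- sort(unique(as.character(table$node)))
  out <- list(); ks <- c()
  for (cam in unique(table$camera)) {
    tc <- table[table$camera == cam, ]
    wide_x <- tidyr::pivot_wider(tc[, c("frame", "node", "x")],
                                 names_from = "node", values_from = "x")
    wide_y <- tidyr::pivot_wider(tc[, c("frame", "node", "y")],
                                 names_from = "node", values_from = "y")
    wide_x <- wide_x[, c("frame", nodes)]; wide_y <- wide_y[, c("frame", nodes)]
    m <- cbind(as.matrix(wide_x[, nodes]), as.matrix(wide_y[, nodes]))
    complete <- stats::complete.cases(m)
    if (sum(complete) < 2L) {
      warn(sprintf("camera %s: fewer than 2 complete frames; PCA stage skipped.", cam))
      next
    }
    mc <- m[complete, , drop = FALSE]
    pc <- prcomp(mc, center = TRUE, scale. = FALSE)
    if (sum(pc$sdev^2) <= 1e-12) {  # identical poses: nothing to reconstruct
      out[[cam]] <- tibble::tibble(
        camera = cam, frame = wide_x$frame[complete],
        recon_error = 0, excluded_pca = FALSE)
      ks[cam] <- 0L
      next
    }
    var_frac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- which(var_frac >= config$pca_mse_drop_fraction)[1]
    scores <- pc$x
    resid2 <- if (k < ncol(scores)) {
      rowSums(scores[, (k + 1):ncol(scores), drop = FALSE]^2)
    } else {
      rep(0, nrow(scores))
    }
    err <- resid2 / ncol(mc)  # per-frame mean squared reconstruction error
    thr <- median(err) + config$pca_outlier_mads * mad(err, constant = 1.4826)
    flag <- err > thr & err > config$pca_min_error
    out[[cam]] <- tibble::tibble(
      camera = cam,
      frame = wide_x$frame[complete],
      recon_error = err,
      excluded_pca = flag
    )
    ks[cam] <- k
  }
  res <- if (length(out)) bind_rows(out) else {
    tibble::tibble(camera = character(), frame = integer(),
                   recon_error = numeric(), excluded_pca = logical())
  }
  attr(res, "n_components") <- ks
  res
}

#' Validity of visible keypoints from fluorescence evidence
#'
#' A visible keypoint is valid when its fluorescence peak meets the
#' confidence-scaled minimum and its distance to the nearest fluorescence
#' center is within the confidence-scaled maximum (see
#' [validity_thresholds()]). Missing evidence renders a keypoint invalid.
#'
#' @param table Tibble with `score`, `peak_value`, `center_dist` columns.
#' @param config A [qc_config()].
#' @return Input plus logical columns `invalid_fluor`, `invalid_distance`,
#'   `valid`.
#' @export
validity_filter <- function(table, config = qc_config()) {
  table <- tibble::as_tibble(table)
  thr <- validity_thresholds(table$score, config)
  table$invalid_fluor <- is.na(table$peak_value) |
    table$peak_value < thr$min_fluor_peak
  table$invalid_distance <- is.na(table$center_dist) |
    table$center_dist > thr$max_center_distance
  table$valid <- !table$invalid_fluor & !table$invalid_distance
  table
}

#' Flag frames containing an implausibly distant keypoint pair
#'
#' @param table Tibble with `camera`, `frame`, `x`, `y` for the keypoints to
#'   check (normally the valid ones).
#' @param max_pair_distance Threshold in pixels; a frame is flagged when any
#'   pair's L2 distance strictly exceeds it.
#' @return Tibble with `camera`, `frame`, `max_pair`, `excluded_pairwise`.
#' @export
pairwise_distance_filter <- function(table, max_pair_distance = qc_config()$max_pair_distance) {
  table <- tibble::as_tibble(table)
  table %>%
    filter(!is.na(.data$x), !is.na(.data$y)) %>%
    group_by(.data$camera, .data$frame) %>%
    summarise(
      max_pair = if (n() < 2L) 0 else max(stats::dist(cbind(.data$x, .data$y))),
      .groups = "drop"
    ) %>%
    mutate(excluded_pairwise = .data$max_pair > max_pair_distance)
}

#' Run the full keypoint quality-control cascade
#'
#' Stages are applied in the fixed published order: jump filter, PCA pose
#' outliers (skipped when `pca_enabled` is off, e.g. for the two-node knee
#' configuration), visibility, confidence-scaled validity, dropped-keypoint
#' budget, and pairwise distance. The surviving dataset contains the valid
#' keypoints of frames that no frame-level stage excluded.
#'
#' @param table Keypoint table with fluorescence evidence columns
#'   `peak_value` (a.u.) and `center_dist` (px), e.g. the output of
#'   [refine_keypoints()] (where `distance_moved` serves as `center_dist`).
#' @param config A [qc_config()].
#' @return A `qdpi_qc_report`: list with `records` (per-record flags),
#'   `frames` (per-frame flags), `counts` (exclusions per reason),
#'   `surviving` (the machine-labeled dataset), `stages` (applied/skipped),
#'   `config`.
#' @export
run_cascade <- function(table, config = qc_config()) {
  table <- tibble::as_tibble(table)
  if (!"center_dist" %in% names(table) && "distance_moved" %in% names(table)) {
    table$center_dist <- table$distance_moved
  }
  need <- c("frame", "camera", "node", "x", "y", "score", "peak_value", "center_dist")
  miss <- setdiff(need, names(table))
  if (length(miss)) abort(paste0("cascade input lacks column(s): ",
                                 paste(miss, collapse = ", ")))

  # stage 1: jump
  rec <- jump_filter(table, config$max_jump)

  # stage 2: PCA pose outliers on records surviving the jump filter
  pca_skipped <- !isTRUE(config$pca_enabled)
  if (!pca_skipped) {
    pca <- pca_outlier_filter(rec[!rec$excluded_jump, ], config)
    rec <- left_join(rec, pca[, c("camera", "frame", "excluded_pca")],
                     by = c("camera", "frame"))
    rec$excluded_pca[is.na(rec$excluded_pca)] <- FALSE
  } else {
    rec$excluded_pca <- FALSE
  }

  # stage 3: visibility
  rec$invisible <- is.na(rec$score) | rec$score <= config$visibility_score |
    is.na(rec$x) | is.na(rec$y)

  # stage 4: confidence-scaled validity (visible, unexcluded records only)
  live <- !rec$excluded_jump & !rec$excluded_pca & !rec$invisible
  v <- validity_filter(rec[live, ], config)
  rec$invalid_fluor <- rec$invalid_distance <- rec$valid <- FALSE
  rec$invalid_fluor[live] <- v$invalid_fluor
  rec$invalid_distance[live] <- v$invalid_distance
  rec$valid[live] <- v$valid

  # stage 5: dropped-keypoint budget per frame
  frames <- rec %>%
    group_by(.data$camera, .data$frame) %>%
    summarise(
      n_visible = sum(!.data$invisible & !.data$excluded_jump & !.data$excluded_pca),
      n_valid = sum(.data$valid),
      excluded_pca_frame = any(.data$excluded_pca),
      .groups = "drop"
    ) %>%
    mutate(
      budget = drop_budget(.data$n_visible, config),
      excluded_drop_budget = (.data$n_visible - .data$n_valid) > .data$budget
    )

  # stage 6: pairwise distance among surviving valid keypoints
  pw_in <- rec[rec$valid, c("camera", "frame", "x", "y")]
  pw <- pairwise_distance_filter(pw_in, config$max_pair_distance)
  frames <- left_join(frames, pw[, c("camera", "frame", "max_pair", "excluded_pairwise")],
                      by = c("camera", "frame"))
  frames$excluded_pairwise[is.na(frames$excluded_pairwise)] <- FALSE
  frames$max_pair[is.na(frames$max_pair)] <- 0

  frame_ok <- frames %>%
    mutate(frame_excluded = .data$excluded_drop_budget | .data$excluded_pairwise |
             .data$excluded_pca_frame) %>%
    select("camera", "frame", "frame_excluded")
  rec <- left_join(rec, frame_ok, by = c("camera", "frame"))
  surviving <- rec[rec$valid & !rec$frame_excluded, , drop = FALSE]

  counts <- tibble::tibble(
    reason = c("jump", "pca", "invisible", "invalid_fluor", "invalid_distance",
               "drop_budget_frames", "pairwise_frames"),
    n = c(sum(rec$excluded_jump), sum(rec$excluded_pca & !rec$excluded_jump),
          sum(rec$invisible & !rec$excluded_jump & !rec$excluded_pca),
          sum(rec$invalid_fluor), sum(rec$invalid_distance),
          sum(frames$excluded_drop_budget), sum(frames$excluded_pairwise))
  )
  structure(
    list(records = rec, frames = frames, counts = counts,
         surviving = surviving,
         stages = tibble::tibble(
           stage = c("jump", "pca", "visibility", "validity", "drop_budget", "pairwise"),
           applied = c(TRUE, !pca_skipped, TRUE, TRUE, TRUE, TRUE)
         ),
         config = config),
    class = "qdpi_qc_report"
  )
}

#' @export
print.qdpi_qc_report <- function(x, ...) {
  cat("<qdpi_qc_report> ", nrow(x$surviving), "/", nrow(x$records),
      " records survive\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.qdpi_qc_report <- function(x, ...) x$counts

#' @export
glance.qdpi_qc_report <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records),
    n_surviving = nrow(x$surviving),
    n_frames = nrow(x$frames),
    n_frames_excluded = sum(x$frames$excluded_drop_budget | x$frames$excluded_pairwise |
                              x$frames$excluded_pca_frame)
  )
}
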