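#' Configuration for the synthetic-data generator
#'
#' One seeded configuration drives every generator. Defaults emulate the
#' study conditions: fluorescent spots with a width of sigma = 3 px (FWHM
#' 2.3548 * sigma ~ 7 px, inside the reported 6-15 px range), spot amplitudes
#' well above background on an 8-bit sensor, exponential session-to-session
#' amplitude decay, and tracker-like keypoint noise whose confidence score
#' falls with true error.
#'
#' @param seed Integer; fixes all randomness.
#' @param shape Frame shape `c(rows, cols)` for rendered recordings.
#' @param n_cycles Illumination cycles (one reflectance + one fluorescence
#'   frame each).
#' @param schedule A `qdpi_schedule`.
#' @param bit_depth 8 or 16.
#' @param sigma Spot Gaussian SD, px.
#' @param amplitude Spot peak amplitude at day 0, a.u.
#' @param background Constant fluorescence background level, a.u.
#' @param read_noise_sd Gaussian read-noise SD, a.u.
#' @param poisson Add Poisson shot noise instead of purely Gaussian noise.
#' @param half_life Amplitude decay half-life, days.
#' @param day Day post-injection of the simulated session.
#' @param motion_amplitude Body-center excursion, px (0 freezes the subject).
#' @param jitter_sd Keypoint prediction jitter SD, px.
#' @param err0 Error scale of the confidence model
#'   `score = clamp(1 - error / err0 + noise, 0, 1)`.
#' @param score_noise_sd SD of the confidence-model noise.
#' @param n_cameras,camera_distance_mm,camera_px_noise Camera-rig generator:
#'   number of cameras on the pentagon, their distance from the arena center
#'   (mm), and observation noise (px).
#' @param enrichment,coloc_ratio Histology generator targets: intracellular
#'   enrichment factor and marker/nucleus colocalization ratio.
#' @param histology_shape Histology field shape.
#' @return A `qdpi_sim_config` list.
#' @export
sim_config <- function(seed = 1L, shape = c(96L, 96L), n_cycles = 50L,
                       schedule = default_schedule(), bit_depth = 8L,
                       sigma = 3, amplitude = 150, background = 10,
                       read_noise_sd = 2, poisson = FALSE,
                       half_life = 5, day = 0,
                       motion_amplitude = 20,
                       jitter_sd = 0.5, err0 = 10, score_noise_sd = 0.05,
                       n_cameras = 5L, camera_distance_mm = 304.8,
                       camera_px_noise = 0,
                       enrichment = 3.7, coloc_ratio = 1.8,
                       histology_shape = c(512L, 512L)) {
  structure(
    list(seed = as.integer(seed), shape = shape, n_cycles = n_cycles,
         schedule = schedule, bit_depth = bit_depth,
         sigma = sigma, amplitude = amplitude, background = background,
         read_noise_sd = read_noise_sd, poisson = poisson,
         half_life = half_life, day = day,
         motion_amplitude = motion_amplitude,
         jitter_sd = jitter_sd, err0 = err0, score_noise_sd = score_noise_sd,
         n_cameras = n_cameras, camera_distance_mm = camera_distance_mm,
         camera_px_noise = camera_px_noise,
         enrichment = enrichment, coloc_ratio = coloc_ratio,
         histology_shape = histology_shape),
    class = "qdpi_sim_config"
  )
}

# fixed skeleton template: 0-based (x, y) offsets from the body center, px.
# Spans ~85 px nose-to-tail at unit scale.
.node_template <- function() {
  tibble::tribble(
    ~node,         ~dx,  ~dy,
    "back_top",      0,   30,
    "back_middle",   0,   10,
    "back_bottom",   0,  -10,
    "tail_base",     0,  -25,
    "tail_middle",   0,  -40,
    "tail_tip",      0,  -55,
    "fore_paw_l",  -15,   20,
    "fore_paw_r",   15,   20,
    "hind_paw_l",  -15,  -15,
    "hind_paw_r",   15,  -15
  )
}

#' Simulate a multiplexed recording with ground truth
#'
#' Renders interleaved reflectance frames (a bright moving body ellipse) and
#' fluorescence frames (Gaussian marker spots on a constant background, with
#' Gaussian read noise and optional Poisson shot noise), following the
#' illumination schedule. Spot amplitude decays exponentially with the
#' session day: `amplitude * 2^(-day / half_life)`.
#'
#' @param config A [sim_config()].
#' @param nodes Marker names to render; defaults to three back spots.
#' @param session A `qdpi_session`; its `day_post_injection` defaults to
#'   `config$day`.
#' @return List: `recording` (a `qdpi_recording`), `truth` with `spots`
#'   (tibble: fluorescence `frame`, `node`, `cx`, `cy`, `sigma`, `amplitude`,
#'   `clipped`), `channels` (tibble: raw `frame`, `channel`) and `body_mask`
#'   (per-cycle logical mask stack of the body ellipse).
#' @export
simulate_recording <- function(config = sim_config(),
                               nodes = c("back_top", "back_middle", "back_bottom"),
                               session = NULL) {
  if (is.null(session)) {
    session <- session_key(day_post_injection = config$day)
  }
  withr::with_seed(config$seed, {
    h <- config$shape[1]; w <- config$shape[2]
    n_cyc <- config$n_cycles
    fpc <- config$schedule$frames_per_cycle
    slots <- config$schedule$channel_of_slot
    maxval <- 2^config$bit_depth - 1
    amp_day <- config$amplitude * 2^(-config$day / config$half_life)
    tmpl <- .node_template() %>% filter(.data$node %in% nodes)
    # scale the template into a small frame, keeping spots well separated
    scale <- min(h, w) / 160
    xs <- matrix(rep(.index_to_px(seq_len(w)), each = h), h)
    ys <- matrix(rep(.index_to_px(seq_len(h)), w), h)
    t_seq <- seq_len(n_cyc) - 1L
    cx_t <- (w - 1) / 2 + config$motion_amplitude * sin(2 * pi * t_seq / 40)
    cy_t <- (h - 1) / 2 + config$motion_amplitude * 0.6 * cos(2 * pi * t_seq / 55)
    frames <- array(0, c(n_cyc * fpc, h, w))
    spots <- vector("list", n_cyc)
    body_mask <- array(FALSE, c(n_cyc, h, w))
    for (ci in seq_len(n_cyc)) {
      centers <- tibble::tibble(
        node = tmpl$node,
        cx = cx_t[ci] + tmpl$dx * scale,
        cy = cy_t[ci] + tmpl$dy * scale,
        sigma = config$sigma,
        amplitude = amp_day
      )
      fluor <- matrix(config$background, h, w)
      for (k in seq_len(nrow(centers))) {
        fluor <- fluor + centers$amplitude[k] *
          exp(-((xs - centers$cx[k])^2 + (ys - centers$cy[k])^2) /
                (2 * centers$sigma[k]^2))
      }
      body <- ((xs - cx_t[ci]) / (34 * scale))^2 +
        ((ys - cy_t[ci]) / (48 * scale))^2 <= 1
      body_mask[ci, , ] <- body
      reflect <- matrix(20, h, w)
      reflect[body] <- 120
      for (s in seq_len(fpc)) {
        base <- if (slots[s] == "reflectance") reflect else fluor
        img <- base
        if (config$poisson) img <- rpois(length(img), pmax(img, 0)) + 0
        if (config$read_noise_sd > 0) {
          img <- img + rnorm(length(img), 0, config$read_noise_sd)
        }
        dim(img) <- c(h, w)
        frames[(ci - 1L) * fpc + s, , ] <- pmin(pmax(round(img), 0), maxval)
      }
      centers$clipped <- centers$cx < 0 | centers$cx > w - 1 |
        centers$cy < 0 | centers$cy > h - 1
      centers$frame <- ci - 1L
      spots[[ci]] <- centers
    }
    truth_spots <- bind_rows(spots)[, c("frame", "node", "cx", "cy",
                                        "sigma", "amplitude", "clipped")]
    channels <- tibble::tibble(
      frame = .index_to_px(seq_len(n_cyc * fpc)),
      channel = rep(slots, n_cyc)
    )
    list(
      recording = multiplexed_recording(frames, config$schedule, session,
                                        bit_depth = config$bit_depth),
      truth = list(spots = truth_spots, channels = channels,
                   body_mask = body_mask)
    )
  })
}

#' Simulate tracker-like keypoint predictions from ground-truth spots
#'
#' Predictions are truth centers plus Gaussian jitter; the confidence score
#' falls linearly with the true localization error
#' (`score = clamp(1 - error / err0 + noise, 0, 1)`). Fluorescence evidence
#' columns emulate a perfect refinement pass: `peak_value` is the spot
#' amplitude plus noise and `center_dist` the prediction's true distance to
#' the spot center. Violations of the QC rules can be injected in configured
#' counts; each injected record is labeled with the rule it violates.
#'
#' @param truth Tibble of ground-truth spots (`frame`, `node`, `cx`, `cy`,
#'   `amplitude`), e.g. from [simulate_recording()].
#' @param config A [sim_config()].
#' @param camera Camera id for the output table.
#' @param violations Named counts: any of `jump`, `low_score`, `low_fluor`,
#'   `far_dist`, `missing`.
#' @return List: `keypoints` (tibble `frame, camera, node, x, y, score,
#'   peak_value, center_dist`), `labels` (tibble `frame, camera, node,
#'   reason`, one row per injected violation).
#' @export
simulate_keypoints <- function(truth, config = sim_config(), camera = "c0",
                               violations = c()) {
  withr::with_seed(config$seed + 1L, {
    n <- nrow(truth)
    errx <- rnorm(n, 0, config$jitter_sd)
    erry <- rnorm(n, 0, config$jitter_sd)
    err <- sqrt(errx^2 + erry^2)
    kp <- tibble::tibble(
      frame = truth$frame,
      camera = camera,
      node = truth$node,
      x = truth$cx + errx,
      y = truth$cy + erry,
      score = pmin(pmax(1 - err / config$err0 +
                          rnorm(n, 0, config$score_noise_sd), 0), 1),
      peak_value = truth$amplitude + rnorm(n, 0, 3),
      center_dist = err
    )
    labels <- tibble::tibble(frame = integer(), camera = character(),
                             node = character(), reason = character())
    used <- integer(0)
    pick <- function(k) {
      # interior records not yet used for another violation
      pool <- setdiff(which(kp$frame > min(kp$frame) & kp$frame < max(kp$frame)),
                      used)
      sel <- pool[sample.int(length(pool), k)]
      used <<- c(used, sel)
      sel
    }
    inject <- function(k, reason, fn) {
      if (is.na(k) || k <= 0) return()
      sel <- pick(k)
      kp <<- fn(kp, sel)
      labels <<- bind_rows(labels, tibble::tibble(
        frame = kp$frame[sel], camera = camera, node = kp$node[sel],
        reason = reason))
    }
    v <- function(nm) if (nm %in% names(violations)) violations[[nm]] else 0
    inject(v("jump"), "jump", function(kp, sel) {
      kp$x[sel] <- kp$x[sel] + 60 / sqrt(2); kp$y[sel] <- kp$y[sel] + 60 / sqrt(2); kp
    })
    inject(v("low_score"), "invisible", function(kp, sel) {
      kp$score[sel] <- 0.05; kp
    })
    inject(v("low_fluor"), "invalid_fluor", function(kp, sel) {
      kp$peak_value[sel] <- 10; kp
    })
    inject(v("far_dist"), "invalid_distance", function(kp, sel) {
      kp$center_dist[sel] <- 25; kp
    })
    inject(v("missing"), "missing", function(kp, sel) {
      kp$x[sel] <- NA_real_; kp$y[sel] <- NA_real_; kp
    })
    list(keypoints = kp, labels = labels)
  })
}

#' Synthetic benchmark for the full quality-control cascade
#'
#' Generates a 10-node keypoint table over `n_frames` frames of smooth pose
#' motion with one deterministic injection per cascade rule, each placed so it
#' triggers exactly its own rule: a 60 px teleport of one record (jump), a
#' 15 px single-node pose deformation (PCA outlier), one record with
#' confidence 0.05 (invisible), one with dim fluorescence evidence (invalid
#' fluorescence), one too far from its fluorescence center (invalid
#' distance), one frame with four dim-evidence keypoints (drop budget), and a
#' smooth tail-stretch excursion that carries a keypoint pair beyond 300 px
#' (pairwise). The stretch is a genuine pose mode present in the data, so the
#' PCA stage reconstructs it instead of flagging it. Ground-truth labels are
#' recomputed from the final table with one-line rule oracles (or recorded by
#' construction for the PCA frame).
#'
#' @param seed Integer seed for the jitter and score noise.
#' @param n_frames Number of frames (default 100).
#' @param jitter_sd Keypoint jitter SD, px.
#' @param inject Inject the violations. `FALSE` produces a clean benchmark:
#'   same pose modes, but with the tail stretch scaled down so no keypoint
#'   pair ever exceeds the pairwise limit (the stretch still carries well
#'   over 10% of the pose variance), and empty label tables.
#' @return List: `keypoints` (cascade-ready tibble), `record_labels`
#'   (tibble `frame, node, reason`), `frame_labels` (tibble `frame, reason`).
#' @export
simulate_qc_benchmark <- function(seed = 1L, n_frames = 100L, jitter_sd = 0.5,
                                  inject = TRUE) {
  withr::with_seed(seed, {
    tmpl <- .node_template()
    t_seq <- seq_len(n_frames) - 1L
    # the two translation modes and the tail-stretch mode follow distinct
    # Fourier harmonics of the window, so they are exactly uncorrelated and
    # each carries well over 10% of the pose variance: the 90% reconstruction
    # rule then always keeps all three, and the stretch (which exceeds the
    # pairwise limit at its peaks) is reconstructed, not flagged, by PCA
    cx_t <- 320 + 60 * sin(2 * pi * t_seq / n_frames)
    cy_t <- 240 + 60 * sin(2 * pi * 3 * t_seq / n_frames)
    stretch_amp <- if (inject) 160 else 120
    stretch <- stretch_amp * (1 - cos(2 * pi * 2 * t_seq / n_frames))
    kp <- tidyr::expand_grid(frame = t_seq, node = tmpl$node) %>%
      left_join(tmpl, by = "node") %>%
      mutate(
        x = cx_t[.data$frame + 1L] + .data$dx +
          ifelse(.data$node == "tail_tip", stretch[.data$frame + 1L], 0),
        y = cy_t[.data$frame + 1L] + .data$dy
      ) %>%
      select(-"dx", -"dy")
    n <- nrow(kp)
    kp$x <- kp$x + rnorm(n, 0, jitter_sd)
    kp$y <- kp$y + rnorm(n, 0, jitter_sd)
    err <- abs(rnorm(n, 0, jitter_sd))
    kp$camera <- "c0"
    kp$score <- pmin(pmax(1 - err / 10 + rnorm(n, 0, 0.03), 0), 1)
    kp$peak_value <- 150 + rnorm(n, 0, 3)
    kp$center_dist <- err
    kp <- kp[, c("frame", "camera", "node", "x", "y", "score",
                 "peak_value", "center_dist")]
    at <- function(f, nd) which(kp$frame == f & kp$node == nd)
    if (inject) {
      # jump: teleport back_top at frame 10
      kp$x[at(10, "back_top")] <- kp$x[at(10, "back_top")] + 60 / sqrt(2)
      kp$y[at(10, "back_top")] <- kp$y[at(10, "back_top")] + 60 / sqrt(2)
      # PCA outlier: deform back_middle at frame 45, orthogonal to the pose
      # modes; 15 px keeps the neighboring steps under the jump limit while
      # the pose reconstruction error is still orders of magnitude above
      # threshold
      kp$y[at(45, "back_middle")] <- kp$y[at(45, "back_middle")] + 15
      # invisible: tail_middle at frame 35
      kp$score[at(35, "tail_middle")] <- 0.05
      # invalid fluorescence: hind_paw_l at frame 40
      kp$peak_value[at(40, "hind_paw_l")] <- 10
      # invalid distance: fore_paw_r at frame 50
      kp$center_dist[at(50, "fore_paw_r")] <- 25
      # drop budget: all four paws dim at frame 60
      for (nd in c("fore_paw_l", "fore_paw_r", "hind_paw_l", "hind_paw_r")) {
        kp$peak_value[at(60, nd)] <- 10
      }
    }

    # ---- rule oracles on the final table ----
    cfg <- qc_config()
    lab <- list()
    kpo <- kp %>% group_by(.data$node) %>% arrange(.data$frame, .by_group = TRUE) %>%
      mutate(dp = sqrt((.data$x - lag(.data$x))^2 + (.data$y - lag(.data$y))^2),
             dn = sqrt((lead(.data$x) - .data$x)^2 + (lead(.data$y) - .data$y)^2)) %>%
      ungroup()
    jump_bad <- kpo[(!is.na(kpo$dp) & kpo$dp > 30) | (!is.na(kpo$dn) & kpo$dn > 30), ]
    lab$jump <- tibble::tibble(frame = jump_bad$frame, node = jump_bad$node,
                               reason = "jump")
    inv <- kp[kp$score <= 0.2, ]
    lab$invisible <- tibble::tibble(frame = inv$frame, node = inv$node,
                                    reason = "invisible")
    s <- pmax(kp$score, 0.7)
    min_peak <- 75 + (s - 0.7) / 0.3 * (25 - 75)
    max_dist <- 5 + (s - 0.7) / 0.3 * (15 - 5)
    live <- kp$score > 0.2 &
      !(paste(kp$frame, kp$node) %in% paste(lab$jump$frame, lab$jump$node))
    if (inject) live <- live & kp$frame != 45L  # the constructed PCA-outlier frame
    bf <- which(live & kp$peak_value < min_peak)
    bd <- which(live & kp$center_dist > max_dist)
    lab$fluor <- tibble::tibble(frame = kp$frame[bf], node = kp$node[bf],
                                reason = "invalid_fluor")
    lab$dist <- tibble::tibble(frame = kp$frame[bd], node = kp$node[bd],
                               reason = "invalid_distance")
    record_labels <- bind_rows(lab)
    # frame-level: drop budget and pairwise among valid keypoints; PCA frame
    # by construction
    valid_idx <- live & !(seq_len(n) %in% c(bf, bd))
    frame_stats <- kp %>%
      mutate(live = live, valid = valid_idx) %>%
      group_by(.data$frame) %>%
      summarise(n_vis = sum(.data$live), n_val = sum(.data$valid),
                max_pair = if (sum(.data$valid) < 2L) 0 else
                  max(stats::dist(cbind(.data$x[.data$valid],
                                        .data$y[.data$valid]))),
                .groups = "drop") %>%
      mutate(budget = floor(pmin(pmax((.data$n_vis - 3) / 7, 0), 1) * 3),
             bad_budget = (.data$n_vis - .data$n_val) > .data$budget,
             bad_pair = .data$max_pair > 300)
    frame_labels <- bind_rows(
      tibble::tibble(frame = frame_stats$frame[frame_stats$bad_budget],
                     reason = "drop_budget"),
      tibble::tibble(frame = frame_stats$frame[frame_stats$bad_pair],
                     reason = "pairwise"),
      if (inject) tibble::tibble(frame = 45L, reason = "pca")
    )
    list(keypoints = kp, record_labels = record_labels,
         frame_labels = frame_labels)
  })
}

#' Simulate a calibrated multi-camera rig and projected trajectory
#'
#' Cameras sit on a regular polygon around the arena center at the configured
#' distance, slightly elevated and aimed at the origin, with intrinsics
#' derived from the standard optics (8 mm lens, 5.7 um pixels). A smooth 3-D
#' trajectory inside the arena is projected into every camera, with optional
#' pixel noise.
#'
#' @param config A [sim_config()].
#' @param n_points Trajectory length (frames).
#' @return List: `cameras` (named `qdpi_camera` list), `points3d` (tibble
#'   `frame, X, Y, Z`, mm), `keypoints` (tibble of per-camera projections).
#' @export
simulate_camera_rig <- function(config = sim_config(), n_points = 50L) {
  if (config$n_cameras < 2L) abort("need at least 2 cameras.")
  withr::with_seed(config$seed + 2L, {
    f_px <- 8 / 5.7e-3  # 8 mm lens over 5.7 um pixels, in px
    K <- matrix(c(f_px, 0, 319.5, 0, f_px, 239.5, 0, 0, 1), 3, 3, byrow = TRUE)
    cameras <- list()
    for (i in seq_len(config$n_cameras)) {
      ang <- 2 * pi * (i - 1) / config$n_cameras
      C <- c(config$camera_distance_mm * cos(ang),
             config$camera_distance_mm * sin(ang), 120)
      z_axis <- -C / sqrt(sum(C^2))                   # toward the origin
      x_axis <- c(-sin(ang), cos(ang), 0)             # horizontal, tangential
      y_axis <- .cross3(z_axis, x_axis)               # image y points down-ish
      R <- rbind(x_axis, y_axis, z_axis)
      cameras[[paste0("c", i - 1L)]] <- camera_model(
        K = K, dist = rep(0, 5), R = R, t = as.numeric(-R %*% C),
        pixel_pitch_um = 5.7, focal_length_mm = 8
      )
    }
    t_seq <- seq_len(n_points) - 1L
    pts <- tibble::tibble(
      frame = t_seq,
      X = 80 * sin(2 * pi * t_seq / 45),
      Y = 60 * cos(2 * pi * t_seq / 37),
      Z = 20 + 15 * sin(2 * pi * t_seq / 29)
    )
    proj <- purrr::map(names(cameras), function(cid) {
      pr <- project_points(cameras[[cid]], as.matrix(pts[, c("X", "Y", "Z")]))
      tibble::tibble(
        frame = pts$frame, camera = cid, node = "body",
        x = pr$x + rnorm(n_points, 0, config$camera_px_noise),
        y = pr$y + rnorm(n_points, 0, config$camera_px_noise),
        score = 1
      )
    }) %>% bind_rows()
    list(cameras = cameras, points3d = pts, keypoints = proj)
  })
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Simulate a histology field with ground-truth ratios
#'
#' Builds a confocal-like field: scattered cell ROIs whose QD intensity is
#' `enrichment` times the extracellular level, one large host cell containing
#' the marker (collagen) region, and a nucleus (DAPI) region outside all
#' cells. The marker disk area is sized so that the marker/nucleus QD-sum
#' ratio matches the configured colocalization ratio. Channel foregrounds are
#' far above background, so Otsu thresholds recover the masks.
#'
#' @param config A [sim_config()].
#' @return List: `field` (a `qdpi_histology_field`), `truth` (tibble with the
#'   configured and realized `enrichment` and `coloc_ratio`, computed on the
#'   noiseless field).
#' @export
simulate_histology <- function(config = sim_config()) {
  withr::with_seed(config$seed + 3L, {
    h <- config$histology_shape[1]; w <- config$histology_shape[2]
    xs <- matrix(rep(seq_len(w), each = h), h)
    ys <- matrix(rep(seq_len(h), w), h)
    disk <- function(cx, cy, r) (xs - cx)^2 + (ys - cy)^2 <= r^2
    bg_qd <- 10
    rn <- 40                                  # nucleus disk radius
    rm <- 40 * sqrt(config$coloc_ratio / config$enrichment)
    host_r <- 60
    if (rm > host_r) {
      warn("marker disk clipped to the host cell; realized colocalization ratio is reduced.")
      rm <- host_r
    }
    roi <- matrix(0L, h, w)
    host <- disk(w * 0.25, h * 0.25, host_r)
    roi[host] <- 1L
    lab <- 1L
    for (i in seq_len(40)) {
      cx <- runif(1, 40, w - 40); cy <- runif(1, h * 0.55, h - 40)
      lab <- lab + 1L
      roi[disk(cx, cy, runif(1, 10, 14)) & roi == 0L] <- lab
    }
    marker_mask <- disk(w * 0.25, h * 0.25, rm)          # inside the host cell
    nucleus_mask <- disk(w * 0.75, h * 0.25, rn)         # outside all cells
    qd0 <- matrix(bg_qd, h, w)
    qd0[roi > 0L] <- bg_qd * config$enrichment
    marker0 <- matrix(20, h, w); marker0[marker_mask] <- 200
    nucleus0 <- matrix(20, h, w); nucleus0[nucleus_mask] <- 200
    noisy <- function(m, sd) pmax(m + rnorm(length(m), 0, sd), 0)
    field <- histology_field(
      qd = matrix(noisy(qd0, 1), h, w),
      marker = matrix(noisy(marker0, 3), h, w),
      nucleus = matrix(noisy(nucleus0, 3), h, w),
      roi_masks = roi,
      field_id = "synthetic0"
    )
    truth <- tibble::tibble(
      enrichment_config = config$enrichment,
      enrichment_true = mean(qd0[roi > 0L]) / mean(qd0[roi == 0L]),
      coloc_config = config$coloc_ratio,
      coloc_true = sum(qd0[marker_mask]) / sum(qd0[nucleus_mask])
    )
    list(field = field, truth = truth)
  })
}
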