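#' Illumination schedule for temporally multiplexed recordings
#'
#' Describes one cycle of the LED multiplexing sequence that interleaves
#' infrared reflectance exposures with near-infrared fluorescence exposures.
#' Each phase is either an exposure (`reflectance_on`, `fluorescence_on`) or a
#' dark gap (`off`); every exposure phase produces one camera frame, so the
#' number of frames per cycle equals the number of exposure phases.
#'
#' @param phases A data frame with columns `label` (one of `reflectance_on`,
#'   `off`, `fluorescence_on`) and `ms` (phase duration, milliseconds).
#' @return An object of class `qdpi_schedule` with elements `phases` (tibble),
#'   `frames_per_cycle` and `channel_of_slot` (character vector mapping the
#'   within-cycle frame slot to `"reflectance"` or `"fluorescence"`).
#' @examples
#' illumination_schedule(data.frame(
#'   label = c("reflectance_on", "off", "fluorescence_on", "off"),
#'   ms = c(10, 1, 23, 1.5)
#' ))
#' @export
illumination_schedule <- function(phases) {
  phases <- tibble::as_tibble(phases)
  if (!all(c("label", "ms") %in% names(phases))) {
    abort("`phases` must have columns `label` and `ms`.")
  }
  ok <- phases$label %in% c("reflectance_on", "off", "fluorescence_on")
  if (!all(ok)) abort(paste0("unknown phase label: ", phases$label[!ok][1]))
  if (any(!is.finite(phases$ms) | phases$ms <= 0)) {
    abort("all phase durations must be positive.")
  }
  if (sum(phases$label == "reflectance_on") != 1L ||
      sum(phases$label == "fluorescence_on") != 1L) {
    abort("schedule must contain exactly one reflectance and one fluorescence exposure per cycle.")
  }
  exposure <- phases$label != "off"
  channel_of_slot <- sub("_on$", "", phases$label[exposure])
  structure(
    list(
      phases = phases,
      frames_per_cycle = sum(exposure),
      channel_of_slot = channel_of_slot
    ),
    class = "qdpi_schedule"
  )
}

#' Default illumination schedules
#'
#' The standard sequence is IR reflectance for 10 ms, 1 ms off, NIR
#' fluorescence excitation for 23 ms, 1.5 ms off. The fast variant shortens
#' exposures to 2 / 1 / 8 / 6 ms.
#'
#' @param fast Use the short-exposure variant.
#' @return A `qdpi_schedule`.
#' @export
default_schedule <- function(fast = FALSE) {
  ms <- if (fast) c(2, 1, 8, 6) else c(10, 1, 23, 1.5)
  illumination_schedule(tibble::tibble(
    label = c("reflectance_on", "off", "fluorescence_on", "off"),
    ms = ms
  ))
}

#' @export
print.qdpi_schedule <- function(x, ...) {
  cat("<qdpi_schedule> ", x$frames_per_cycle, " frames/cycle; phases: ",
      paste0(x$phases$label, " (", x$phases$ms, " ms)", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Session identity for a recording
#'
#' @param mouse_id,camera_id Character identifiers.
#' @param day_post_injection Non-negative number of days since marker injection.
#' @param variant_label Marker variant (e.g. `"QD800.3"`, `"vehicle"`, `"blank"`).
#' @return A `qdpi_session` list.
#' @export
session_key <- function(mouse_id = "m0", camera_id = "c0",
                        day_post_injection = 0, variant_label = "QD800.3") {
  if (!is.finite(day_post_injection) || day_post_injection < 0) {
    abort("`day_post_injection` must be >= 0.")
  }
  structure(
    list(mouse_id = as.character(mouse_id), camera_id = as.character(camera_id),
         day_post_injection = as.numeric(day_post_injection),
         variant_label = as.character(variant_label)),
    class = "qdpi_session"
  )
}

#' Multiplexed recording of interleaved reflectance/fluorescence frames
#'
#' @param frames 3-D numeric array with dimensions (frame, row, col); unsigned
#'   intensities within the stated bit depth.
#' @param schedule A `qdpi_schedule`.
#' @param session A `qdpi_session`.
#' @param bit_depth 8 or 16; inferred from the data maximum when `NULL`.
#' @return A `qdpi_recording` list with elements `frames`, `schedule`,
#'   `session`, `bit_depth`.
#' @export
multiplexed_recording <- function(frames, schedule = default_schedule(),
                                  session = session_key(), bit_depth = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a 3-D array (frame, row, col).")
  }
  storage.mode(frames) <- "double"
  if (dim(frames)[1] < 1L) abort("recording must contain at least one frame.")
  if (any(!is.finite(frames)) || any(frames < 0)) {
    abort("frame intensities must be finite and non-negative.")
  }
  if (is.null(bit_depth)) bit_depth <- if (max(frames) > 255) 16L else 8L
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16.")
  if (max(frames) > 2^bit_depth - 1) {
    abort("intensities exceed the stated bit depth.")
  }
  stopifnot(inherits(schedule, "qdpi_schedule"), inherits(session, "qdpi_session"))
  structure(
    list(frames = frames, schedule = schedule, session = session,
         bit_depth = as.integer(bit_depth)),
    class = "qdpi_recording"
  )
}

#' @export
print.qdpi_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat("<qdpi_recording> ", d[1], " frames of ", d[2], "x", d[3], " (",
      x$bit_depth, "-bit), mouse ", x$session$mouse_id, ", camera ",
      x$session$camera_id, ", day ", x$session$day_post_injection, "\n", sep = "")
  invisible(x)
}

#' Split a multiplexed recording into reflectance and fluorescence stacks
#'
#' Frames are assigned to channels by their within-cycle slot according to the
#' illumination schedule. A trailing partial cycle is dropped with a warning
#' rather than an error, since recordings routinely end mid-cycle.
#'
#' @param recording A `qdpi_recording`.
#' @return A list with `reflectance` and `fluorescence` stacks (3-D arrays,
#'   channel order preserved) and `assignment`, a tibble mapping every input
#'   frame (0-based `frame`) to its `channel` (`"dropped"` for a trailing
#'   partial cycle) and its 0-based index `channel_frame` within its channel.
#' @examples
#' rec <- multiplexed_recording(array(0, c(4, 2, 2)))
#' demultiplex(rec)$assignment
#' @export
demultiplex <- function(recording) {
  stopifnot(inherits(recording, "qdpi_recording"))
  fpc <- recording$schedule$frames_per_cycle
  n <- dim(recording$frames)[1]
  n_full <- (n %/% fpc) * fpc
  if (n_full < n) {
    warn(sprintf("dropping %d trailing frame(s) of a partial illumination cycle.",
                 n - n_full))
  }
  if (n_full == 0L) abort("recording shorter than one illumination cycle.")
  slot <- rep(seq_len(fpc), length.out = n_full)
  channel <- rep("dropped", n)
  channel[seq_len(n_full)] <- recording$schedule$channel_of_slot[slot]
  assignment <- tibble::tibble(
    frame = .index_to_px(seq_len(n)),
    channel = channel
  ) %>%
    group_by(.data$channel) %>%
    mutate(channel_frame = ifelse(.data$channel == "dropped", NA_integer_,
                                  row_number() - 1L)) %>%
    ungroup()
  pick <- function(ch) {
    idx <- which(channel == ch)
    recording$frames[idx, , , drop = FALSE]
  }
  list(
    reflectance = pick("reflectance"),
    fluorescence = pick("fluorescence"),
    assignment = assignment
  )
}

#' Alpha-blend a reflectance and a fluorescence frame
#'
#' Produces the display frames used for hand labeling and tracking:
#' `alpha * fluorescence + (1 - alpha) * reflectance`, clipped (saturating) to
#' the given bit depth. The standard mix is 90% fluorescence, 10% reflectance.
#'
#' @param reflectance,fluorescence Equal-shaped numeric matrices.
#' @param alpha Fluorescence weight in \[0, 1\]; default 0.9.
#' @param bit_depth Output clip range, 8 or 16 bit.
#' @return Blended matrix.
#' @export
blend_channels <- function(reflectance, fluorescence, alpha = 0.9, bit_depth = 8L) {
  if (!identical(dim(reflectance), dim(fluorescence))) {
    abort("reflectance and fluorescence frames must have identical shapes.")
  }
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  out <- alpha * fluorescence + (1 - alpha) * reflectance
  pmin(pmax(out, 0), 2^bit_depth - 1)
}

#' Construct and validate a keypoint prediction table
#'
#' The package-wide currency for tracker output: one row per
#' (frame, camera, node) with 0-based pixel coordinates and a confidence
#' score. Missing detections carry `NA` coordinates.
#'
#' @param records Data frame with columns `frame`, `camera`, `node`, `x`, `y`,
#'   `score`.
#' @param node_set Optional ordered character vector of node names; defaults to
#'   the nodes present.
#' @return A validated tibble with attribute `node_set`.
#' @export
keypoint_table <- function(records, node_set = NULL) {
  records <- tibble::as_tibble(records)
  need <- c("frame", "camera", "node", "x", "y", "score")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("keypoint table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  bad <- which(!is.na(records$score) & (records$score < 0 | records$score > 1))
  if (length(bad)) {
    abort(sprintf("confidence score outside [0, 1] at row %d (score = %g).",
                  bad[1], records$score[bad[1]]))
  }
  bad_xy <- which((!is.na(records$x) & !is.finite(records$x)) |
                    (!is.na(records$y) & !is.finite(records$y)))
  if (length(bad_xy)) abort(sprintf("non-finite coordinate at row %d.", bad_xy[1]))
  dup <- duplicated(records[, c("frame", "camera", "node")])
  if (any(dup)) abort(sprintf("duplicate (frame, camera, node) at row %d.",
                              which(dup)[1]))
  if (is.null(node_set)) node_set <- unique(as.character(records$node))
  unknown <- setdiff(unique(records$node), node_set)
  if (length(unknown)) abort(paste0("unknown node name(s): ",
                                    paste(unknown, collapse = ", ")))
  attr(records, "node_set") <- node_set
  records
}

# ---- readers / writers -----------------------------------------------------

#' Read and write illumination schedules as JSON
#'
#' The on-disk form is `{"phases": [{"label": ..., "ms": ...}, ...]}`.
#'
#' @param path File path.
#' @param schedule A `qdpi_schedule`.
#' @return `read_schedule` returns a `qdpi_schedule`; `write_schedule` returns
#'   `path` invisibly.
#' @export
read_schedule <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  illumination_schedule(x$phases)
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "qdpi_schedule"))
  jsonlite::write_json(list(phases = schedule$phases), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write multiplexed recordings
#'
#' A recording is stored as a multi-page TIFF (8- or 16-bit) together with a
#' JSON schedule descriptor. Pixel data round-trip bit-exactly.
#'
#' @param path TIFF file path.
#' @param schedule_path Path of the schedule JSON; defaults to
#'   `<path without extension>_schedule.json`.
#' @param session A `qdpi_session` for the returned recording.
#' @param recording A `qdpi_recording` to write.
#' @return `read_recording` returns a `qdpi_recording`; `write_recording`
#'   returns `path` invisibly.
#' @export
read_recording <- function(path, schedule_path = NULL, session = session_key()) {
  schedule_path <- schedule_path %||% .schedule_sidecar(path)
  schedule <- if (file.exists(schedule_path)) read_schedule(schedule_path) else default_schedule()
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  same <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
  if (!all(same)) abort("inconsistent frame shapes in TIFF stack.")
  frames <- array(0, c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  bit_depth <- attr(pages[[1]], "bits.per.sample") %||% (if (max(frames) > 255) 16L else 8L)
  multiplexed_recording(frames, schedule, session, bit_depth = as.integer(bit_depth))
}

#' @rdname read_recording
#' @export
write_recording <- function(recording, path, schedule_path = NULL) {
  stopifnot(inherits(recording, "qdpi_recording"))
  schedule_path <- schedule_path %||% .schedule_sidecar(path)
  maxval <- 2^recording$bit_depth - 1
  pages <- lapply(seq_len(dim(recording$frames)[1]), function(i) {
    recording$frames[i, , ] / maxval
  })
  tiff::writeTIFF(pages, path, bits.per.sample = recording$bit_depth)
  write_schedule(recording$schedule, schedule_path)
  invisible(path)
}

.schedule_sidecar <- function(path) {
  paste0(sub("\\.[Tt][Ii][Ff][Ff]?$", "", path), "_schedule.json")
}

#' Read and write keypoint tables as CSV
#'
#' Dialect: header `frame,camera,node,x,y,score`; missing keypoints are
#' encoded with empty `x`/`y` fields. Validation errors name the offending
#' row.
#'
#' @param path CSV path.
#' @param table A keypoint table (see [keypoint_table()]).
#' @param node_set Optional ordered node names for validation.
#' @return `read_keypoints` returns a validated tibble; `write_keypoints`
#'   returns `path` invisibly.
#' @export
read_keypoints <- function(path, node_set = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame = "integer", camera = "character",
                                       node = "character", x = "numeric",
                                       y = "numeric", score = "numeric"))
  keypoint_table(df, node_set = node_set)
}

#' @rdname read_keypoints
#' @export
write_keypoints <- function(table, path) {
  table <- keypoint_table(table)
  utils::write.csv(table[, c("frame", "camera", "node", "x", "y", "score")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write camera calibrations as JSON
#'
#' Each camera is stored as `{K (row-major 3x3), dist, R (row-major 3x3),
#' t (mm), pixel_pitch_um, focal_length_mm}` under its camera id.
#'
#' @param path JSON path.
#' @param cameras Named list of `qdpi_camera` objects.
#' @return `read_calibration` returns a named list of `qdpi_camera`;
#'   `write_calibration` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  out <- lapply(x, function(cm) {
    camera_model(
      K = matrix(unlist(cm$K), 3, 3, byrow = TRUE),
      dist = as.numeric(unlist(cm$dist)),
      R = matrix(unlist(cm$R), 3, 3, byrow = TRUE),
      t = as.numeric(unlist(cm$t)),
      pixel_pitch_um = cm$pixel_pitch_um,
      focal_length_mm = cm$focal_length_mm
    )
  })
  stats::setNames(out, names(x))
}

#' @rdname read_calibration
#' @export
write_calibration <- function(cameras, path) {
  ser <- lapply(cameras, function(cm) {
    list(
      K = apply(cm$K, 1, as.numeric, simplify = FALSE),
      dist = as.numeric(cm$dist),
      R = apply(cm$R, 1, as.numeric, simplify = FALSE),
      t = as.numeric(cm$t),
      pixel_pitch_um = cm$pixel_pitch_um,
      focal_length_mm = cm$focal_length_mm
    )
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write analysis configuration files (YAML)
#'
#' @param path YAML path.
#' @param config A named list.
#' @return `read_config` returns a named list; `write_config` returns `path`
#'   invisibly.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
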