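#' Otsu threshold of an image
#'
#' Classic 256-bin histogram threshold maximizing between-class variance.
#' Images of any range (8- or 16-bit, or float) are binned over their own
#' min-max range; the returned threshold is in the original intensity units,
#' with foreground defined as strictly-greater pixels.
#'
#' @param image Numeric matrix with at least 2 distinct values.
#' @param n_bins Histogram bins (default 256).
#' @return Scalar threshold; attribute `"bin"` records the winning cut index
#'   (0-based, last bin of the background class).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) abort("constant image; Otsu threshold undefined.")
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L)  # 0 .. n_bins-1
  counts <- tabulate(bin + 1L, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (seq_len(n_bins) - 0.5)  # bin midpoints on the bin scale
  omega <- cumsum(p)                       # class-0 weight for cut k = bin index
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  # between-class variance for every cut (class 0 = bins <= k)
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  k <- which.max(sigma_b)  # 1-based index of the last background bin
  thr <- lo + k / n_bins * (hi - lo)  # upper edge of bin k-1 (0-based k-1)
  structure(thr, bin = k - 1L)
}

#' Bundle confocal channels into a histology field
#'
#' @param qd QD fluorescence channel (numeric matrix).
#' @param marker Antibody-target channel (collagen or membrane stain).
#' @param nucleus Nuclear stain channel (DAPI).
#' @param roi_masks Optional labeled integer matrix of cell regions (0 =
#'   background).
#' @param field_id Identifier.
#' @return A `qdpi_histology_field` list.
#' @export
histology_field <- function(qd, marker = NULL, nucleus = NULL,
                            roi_masks = NULL, field_id = "field0") {
  chans <- list(qd = qd, marker = marker, nucleus = nucleus, roi_masks = roi_masks)
  shp <- dim(qd)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.null(ch) && !identical(dim(ch), shp)) {
      abort(paste0("channel `", nm, "` shape differs from the QD channel."))
    }
  }
  if (!is.null(roi_masks) && any(roi_masks < 0)) {
    abort("ROI labels must be non-negative integers.")
  }
  structure(c(chans, list(field_id = field_id)), class = "qdpi_histology_field")
}

#' @export
print.qdpi_histology_field <- function(x, ...) {
  cat("<qdpi_histology_field> ", x$field_id, ": ", nrow(x$qd), "x", ncol(x$qd),
      "; channels: ", paste(names(Filter(Negate(is.null),
        x[c("qd", "marker", "nucleus", "roi_masks")])), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Intracellular enrichment ratio of QD fluorescence
#'
#' Mean QD intensity over cell-ROI pixels divided by mean QD intensity over
#' the complement. The default pools all ROI pixels; `per_roi = TRUE` instead
#' averages per-ROI means before dividing by the outside mean.
#'
#' @param field A `qdpi_histology_field` with `roi_masks`, or a numeric QD
#'   matrix (then `roi_masks` must be supplied).
#' @param roi_masks Labeled matrix when `field` is a plain matrix.
#' @param per_roi Average per-ROI means instead of pooling ROI pixels.
#' @return Scalar ratio; `Inf` (with a warning) when all signal is inside the
#'   ROIs so the outside mean is zero.
#' @export
cell_enrichment_ratio <- function(field, roi_masks = NULL, per_roi = FALSE) {
  if (inherits(field, "qdpi_histology_field")) {
    qd <- field$qd; roi_masks <- field$roi_masks
  } else {
    qd <- field
  }
  if (is.null(roi_masks)) abort("cell ROI masks are required.")
  inside <- roi_masks > 0
  if (!any(inside)) abort("ROI mask is empty.")
  if (all(inside)) abort("ROI mask covers the full frame; no outside pixels.")
  outside_mean <- mean(qd[!inside])
  inside_mean <- if (per_roi) {
    labs <- sort(unique(roi_masks[inside]))
    mean(vapply(labs, function(l) mean(qd[roi_masks == l]), numeric(1)))
  } else {
    mean(qd[inside])
  }
  if (outside_mean <= 0) {
    warn("outside-ROI mean is zero; enrichment ratio is infinite.")
    return(Inf)
  }
  inside_mean / outside_mean
}

#' Marker/nucleus colocalization ratio of QD fluorescence
#'
#' Otsu-thresholds the marker and nucleus channels into masks and reports the
#' ratio of total QD intensity within the marker mask to total QD intensity
#' within the nucleus mask. Pixels in both masks count in both by default;
#' `exclusive = TRUE` drops the overlap from both masks.
#'
#' @param field A `qdpi_histology_field` with `marker` and `nucleus` channels.
#' @param exclusive Drop marker-and-nucleus overlap pixels from both masks.
#' @return Scalar ratio.
#' @export
colocalization_ratio <- function(field, exclusive = FALSE) {
  stopifnot(inherits(field, "qdpi_histology_field"))
  if (is.null(field$marker) || is.null(field$nucleus)) {
    abort("marker and nucleus channels are required.")
  }
  marker_mask <- field$marker > otsu_threshold(field$marker)
  nucleus_mask <- field$nucleus > otsu_threshold(field$nucleus)
  if (exclusive) {
    overlap <- marker_mask & nucleus_mask
    marker_mask <- marker_mask & !overlap
    nucleus_mask <- nucleus_mask & !overlap
  }
  if (!any(nucleus_mask)) abort("nucleus mask is empty; ratio undefined.")
  denom <- sum(field$qd[nucleus_mask])
  if (denom <= 0) abort("no QD intensity within the nucleus mask; ratio undefined.")
  sum(field$qd[marker_mask]) / denom
}
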