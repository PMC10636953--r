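#' Preprocessing configuration
#'
#' HU window used before the network: values are clipped to
#' `[hu_window[1], hu_window[2]]` and rescaled to `[0, 1]`. Each prediction
#' uses the target slice plus its two neighbours as a 3-channel slab.
#'
#' @param hu_window clip window in HU, default `c(-140, 210)`.
#' @param slab_radius neighbour slices per side (fixed at 1 = 3 channels).
#' @export
preprocess_config <- function(hu_window = c(-140, 210), slab_radius = 1L) {
  if (hu_window[1] >= hu_window[2]) stop("hu_window must satisfy low < high")
  if (slab_radius != 1L) stop("slab_radius is fixed at 1 (3-channel slab)")
  list(hu_window = as.numeric(hu_window), slab_radius = 1L)
}

#' Clip and normalize a CT volume
#'
#' `v -> (clamp(v, low, high) - low) / (high - low)`, mapping the clip window
#' to `[0, 1]`.
#'
#' @param ct a [ct_volume()] (or bare numeric array of HU).
#' @param cfg a [preprocess_config()].
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
clip_normalize <- function(ct, cfg = preprocess_config()) {
  v <- if (inherits(ct, "ct_volume")) ct$voxels else ct
  lo <- cfg$hu_window[1]; hi <- cfg$hu_window[2]
  (pmin(pmax(v, lo), hi) - lo) / (hi - lo)
}

#' Extract a 3-channel slab
#'
#' Channels are slices `(i - 1, i, i + 1)`; out-of-range neighbours are
#' replaced by edge replication.
#'
#' @param nv normalized volume array `[row, col, slice]`.
#' @param slice_index 1-based target slice.
#' @return `[row, col, 3]` array.
#' @export
make_slab <- function(nv, slice_index) {
  n <- dim(nv)[3]
  if (slice_index < 1 || slice_index > n) stop("slice_index outside volume")
  idx <- pmin(pmax(slice_index + (-1:1), 1), n)
  nv[, , idx, drop = FALSE]
}

#' Heatmap target specification
#'
#' Supervision targets are unnormalized Gaussians (peak 1 at the marker) of
#' width `sigma` mm, one channel per marker (medial, lateral).
#'
#' @param sigma Gaussian width in mm (default 5, the scale of the 5 mm
#'   evaluation tolerance).
#' @export
heatmap_spec <- function(sigma = 5) {
  if (sigma <= 0) stop("sigma must be > 0")
  list(sigma = as.numeric(sigma), n_channels = 2L)
}

#' Build per-slice heatmap targets
#'
#' @param markers 2x2 matrix (rows medial, lateral; cols x, y in mm) or `NULL`
#'   for a marker-free slice (all-zero channels).
#' @param geom any volume-like object carrying the slice geometry (dims,
#'   spacing, origin), e.g. a [ct_volume()].
#' @param spec a [heatmap_spec()].
#' @return `[row, col, 2]` array of targets.
#' @export
make_heatmap_target <- function(markers, geom, spec = heatmap_spec()) {
  d <- dim(geom$voxels)
  out <- array(0, dim = c(d[1], d[2], 2L))
  if (is.null(markers)) return(out)
  cc <- slice_coords(geom)
  for (ch in 1:2) {
    mx <- markers[ch, 1]; my <- markers[ch, 2]
    if (mx < min(cc$x) || mx > max(cc$x) || my < min(cc$y) || my > max(cc$y))
      stop("marker outside image bounds")
    dx2 <- (cc$x - mx)^2
    dy2 <- (cc$y - my)^2
    out[, , ch] <- exp(-(outer(dy2, dx2, `+`)) / (2 * spec$sigma^2))
  }
  out
}

#' Decode heatmaps to marker points
#'
#' Per channel, the argmax pixel is converted to patient mm and the maximum
#' value is the confidence; channels whose maximum is below
#' `confidence_threshold` emit no point. Ties break to the lowest row index,
#' then the lowest column index.
#'
#' @param hm `[row, col, 2]` heatmap array.
#' @param geom slice geometry carrier (as in [make_heatmap_target()]).
#' @param slice 0-based slice index recorded in the output.
#' @param confidence_threshold minimum peak value (default 0.1).
#' @return A [marker_set()] (with `confidence`), possibly empty.
#' @export
decode_heatmaps <- function(hm, geom, slice = 0L, confidence_threshold = 0.1) {
  stopifnot(all(is.finite(hm)))
  rows <- list()
  for (ch in 1:2) {
    m <- hm[, , ch]
    peak <- max(m)
    if (peak < confidence_threshold) next
    # column-major which(): first index is lowest column then lowest row;
    # enforce row-then-column tie-break explicitly
    idx <- which(m == peak, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    mm <- voxel_to_mm(geom, idx[1, 1], idx[1, 2])
    rows[[length(rows) + 1L]] <- data.frame(
      slice = as.integer(slice), channel = c("medial", "lateral")[ch],
      x = mm$x, y = mm$y, confidence = peak
    )
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = integer(0), channel = character(0),
               x = numeric(0), y = numeric(0), confidence = numeric(0))
  marker_set(df, midline_x = NULL) # channels are the network's, keep them
}

#' Classical high-density wire detector
#'
#' A training-free oracle detector exploiting the wire's extreme contrast:
#' per slice, connected components of voxels above `hu_threshold` become
#' candidate points at their centroids; when more than two components exist,
#' the two most extreme in x are kept. Channels follow the medial/lateral
#' convention.
#'
#' @param ct a [ct_volume()].
#' @param hu_threshold HU threshold (default 1500, between bone and lead).
#' @return A [marker_set()] with `confidence` 1 for every emitted point.
#' @export
classical_detect <- function(ct, hu_threshold = 1500) {
  d <- dim(ct$voxels)
  rows <- list()
  for (k in seq_len(d[3])) {
    bw <- ct$voxels[, , k] > hu_threshold
    if (!any(bw)) next
    lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bw)))))
    cents <- lapply(seq_len(max(lab)), function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      mm <- voxel_to_mm(ct, mean(idx[, 1]), mean(idx[, 2]))
      c(mm$x, mm$y)
    })
    if (length(cents) < 2L) next
    xs <- vapply(cents, `[`, numeric(1), 1)
    if (length(cents) > 2L) cents <- cents[c(which.min(xs), which.max(xs))]
    df <- data.frame(
      slice = k - 1L, channel = c("medial", "lateral"),
      x = vapply(cents, `[`, numeric(1), 1),
      y = vapply(cents, `[`, numeric(1), 2),
      confidence = 1
    )
    rows[[length(rows) + 1L]] <- df
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = integer(0), channel = character(0),
               x = numeric(0), y = numeric(0), confidence = numeric(0))
  marker_set(df, midline_x = 0)
}

#' Run a trained detector over a CT volume
#'
#' Applies [clip_normalize()], [make_slab()], the network forward pass and
#' [decode_heatmaps()] to every slice.
#'
#' @param model a `detector_model` from [train_detector()].
#' @param ct a [ct_volume()].
#' @param preprocess a [preprocess_config()].
#' @param confidence_threshold passed to [decode_heatmaps()].
#' @return A [marker_set()] of detections with confidences.
#' @export
detect_markers <- function(model, ct, preprocess = preprocess_config(),
                           confidence_threshold = 0.1) {
  stopifnot(inherits(model, "detector_model"))
  if (max(abs(ct$pixel_spacing - model$pixel_spacing)) > 1e-6)
    warning("pixel spacing differs from the training geometry")
  nv <- clip_normalize(ct, preprocess)
  d <- dim(nv)
  out <- list()
  for (k in seq_len(d[3])) {
    slab <- make_slab(nv, k)
    hm <- net_forward(model$params, slab, train = FALSE)$out
    det <- decode_heatmaps(hm, ct, slice = k - 1L,
                           confidence_threshold = confidence_threshold)
    if (nrow(det) > 0) out[[length(out) + 1L]] <- as.data.frame(det)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(slice = integer(0), channel = character(0),
               x = numeric(0), y = numeric(0), confidence = numeric(0))
  marker_set(df, midline_x = NULL)
}
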