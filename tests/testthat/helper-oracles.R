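# Small phantoms for fast unit tests
tiny_spec <- function(...) {
  args <- utils::modifyList(list(
    body_semiaxes = c(80, 60), lung_semiaxes = c(26, 34),
    lung_center_offset = c(34, 4), breast_radius = 16,
    n_slices = 5, pixel_spacing = 3, noise_sd = 0,
    annotation_jitter_sd = 0, seed = 0
  ), list(...))
  do.call(phantom_spec, args)
}

# Brute-force per-voxel organ-feature oracle, written independently of the
# implementation: side tests via explicit cross products against the line
# through the two (shifted) marker points, looping voxel by voxel.
feature_oracle <- function(mask, markers, shift = 5) {
  d <- dim(mask$voxels)
  num_px <- 0
  for (s in marker_slices(markers)) {
    k <- s + 1L
    if (k < 1L || k > d[3]) next
    mp <- marker_pair(markers, s)
    msl <- mask$voxels[, , k]
    if (is.null(mp) || !any(msl == 1)) next
    idx <- which(msl == 1, arr.ind = TRUE)
    xs <- mask$origin[["x"]] + (idx[, 2] - 1) * mask$pixel_spacing[2]
    ys <- mask$origin[["y"]] + (idx[, 1] - 1) * mask$pixel_spacing[1]
    cx <- sum(xs) / length(xs); cy <- sum(ys) / length(ys)
    p1 <- as.numeric(mp[1, ]); p2 <- as.numeric(mp[2, ])
    cross <- function(a, b, px, py) (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    sc <- sign(cross(p1, p2, cx, cy))
    # translate both marker points 'shift' mm towards the centroid side
    nv <- c(-(p2[2] - p1[2]), p2[1] - p1[1])
    nv <- nv / sqrt(sum(nv^2))
    if (sign(nv[1] * (cx - p1[1]) + nv[2] * (cy - p1[2])) < 0) nv <- -nv
    q1 <- p1 + shift * nv; q2 <- p2 + shift * nv
    for (i in seq_along(xs)) {
      v <- cross(q1, q2, xs[i], ys[i])
      if (sign(v) != sc) num_px <- num_px + 1 # includes v == 0: on-line counts exposed
    }
  }
  num_px / sum(mask$voxels == 1)
}

# Independent channel-respecting matcher: explicit loops over slices/channels
brute_match_counts <- function(pred, gt, tol) {
  pred <- as.data.frame(pred); gt <- as.data.frame(gt)
  tp <- 0L; fp <- 0L; fn <- 0L
  keys <- unique(rbind(pred[c("slice", "channel")], gt[c("slice", "channel")]))
  for (i in seq_len(nrow(keys))) {
    p <- pred[pred$slice == keys$slice[i] & pred$channel == keys$channel[i], ]
    g <- gt[gt$slice == keys$slice[i] & gt$channel == keys$channel[i], ]
    if (nrow(p) == 1 && nrow(g) == 1) {
      d <- sqrt((p$x - g$x)^2 + (p$y - g$y)^2)
      if (d <= tol) tp <- tp + 1L else { fp <- fp + 1L; fn <- fn + 1L }
    } else if (nrow(p) == 1) fp <- fp + 1L
    else if (nrow(g) == 1) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

# random marker sets for metric property tests
random_marker_set <- function(n_slices, p_missing = 0.2, jitter = 4, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_slices) - 1L) for (ch in c("medial", "lateral")) {
    if (runif(1) < p_missing) next
    rows[[length(rows) + 1L]] <- data.frame(
      slice = s, channel = ch,
      x = runif(1, -80, 80) + rnorm(1, 0, jitter),
      y = runif(1, -60, 60)
    )
  }
  marker_set(do.call(rbind, rows), midline_x = NULL)
}
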