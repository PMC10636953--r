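#' Digital thorax phantom specification
#'
#' Parameters of a seeded synthetic axial thorax: an elliptical body with
#' smooth cranio-caudal tapering, two low-density lungs, a rib rim, an
#' ipsilateral breast bulge on the body surface, and two radio-opaque
#' lead-wire marker voxels at the medial and lateral breast borders of every
#' breast-bearing slice. All lengths are millimetres.
#'
#' The breast bulge spans the surface arc from `breast_center_angle - 40` deg
#' (medial border, near the sternum) to
#' `breast_center_angle + 45 + 65 * marker_depth_frac` deg (lateral border),
#' angles measured from the anterior midline towards the ipsilateral side.
#' `marker_depth_frac` therefore controls how deep the chord through the two
#' markers — the tangential field edge — cuts into the lung.
#'
#' @param body_semiaxes body ellipse semiaxes (lateral, anteroposterior), mm.
#' @param lung_semiaxes lung ellipse semiaxes (lateral, anteroposterior), mm.
#' @param lung_center_offset lung centre offset from body centre
#'   (|lateral|, posterior), mm; the two lungs are mirrored in x.
#' @param breast_radius peak height of the breast bulge, mm; 0 removes the
#'   breast (and with it all markers).
#' @param breast_center_angle centre of the breast on the body surface,
#'   degrees from the anterior midline towards the ipsilateral side.
#' @param side `"left"` or `"right"`; the ipsilateral side.
#' @param n_slices number of axial slices.
#' @param slice_thickness slice spacing, mm.
#' @param pixel_spacing in-plane pixel size, mm (isotropic scalar or
#'   (row, col) pair).
#' @param hu_values named list of tissue HU values.
#' @param marker_depth_frac in `[0, 1]`; see Description.
#' @param breast_slice_frac fraction (of the cranio-caudal half-range) of
#'   slices bearing the breast.
#' @param wire_voxels 1 or 3: voxel extent of each rendered wire point.
#' @param noise_sd additive Gaussian HU noise, sd.
#' @param annotation_jitter_sd Gaussian jitter (mm, per coordinate) applied to
#'   the stored annotations relative to the true wire centroids.
#' @param seed integer RNG seed; the phantom is a pure function of the spec.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(body_semiaxes = c(120, 85),
                         lung_semiaxes = c(40, 55),
                         lung_center_offset = c(54, 8),
                         breast_radius = 25,
                         breast_center_angle = 40,
                         side = c("left", "right"),
                         n_slices = 20,
                         slice_thickness = 5,
                         pixel_spacing = 1,
                         hu_values = list(air = -1000, lung = -750,
                                          soft_tissue = 40, bone_rim = 700,
                                          lead_wire = 2500),
                         marker_depth_frac = 0.5,
                         breast_slice_frac = 0.6,
                         wire_voxels = 1,
                         noise_sd = 10,
                         annotation_jitter_sd = 0,
                         seed = 0) {
  side <- match.arg(side)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  spec <- list(
    body_semiaxes = as.numeric(body_semiaxes),
    lung_semiaxes = as.numeric(lung_semiaxes),
    lung_center_offset = as.numeric(lung_center_offset),
    breast_radius = as.numeric(breast_radius),
    breast_center_angle = as.numeric(breast_center_angle),
    side = side, n_slices = as.integer(n_slices),
    slice_thickness = as.numeric(slice_thickness),
    pixel_spacing = as.numeric(pixel_spacing),
    hu_values = hu_values,
    marker_depth_frac = as.numeric(marker_depth_frac),
    breast_slice_frac = as.numeric(breast_slice_frac),
    wire_voxels = as.integer(wire_voxels),
    noise_sd = as.numeric(noise_sd),
    annotation_jitter_sd = as.numeric(annotation_jitter_sd),
    seed = as.integer(seed)
  )
  validate_phantom_spec(spec)
  class(spec) <- "phantom_spec"
  spec
}

validate_phantom_spec <- function(s) {
  pos <- c(s$body_semiaxes, s$lung_semiaxes, s$slice_thickness, s$pixel_spacing)
  if (any(pos <= 0)) stop("lengths and spacings must be strictly positive")
  if (s$n_slices < 1L) stop("n_slices must be >= 1")
  if (s$breast_radius < 0) stop("breast_radius must be >= 0")
  if (s$marker_depth_frac < 0 || s$marker_depth_frac > 1)
    stop("marker_depth_frac must lie in [0, 1]")
  if (!s$wire_voxels %in% c(1L, 3L)) stop("wire_voxels must be 1 or 3")
  if (s$noise_sd < 0 || s$annotation_jitter_sd < 0) stop("noise sds must be >= 0")
  # lung-inside-body: max over the lung boundary of the body ellipse equation
  th <- seq(0, 2 * pi, length.out = 181)
  bx <- abs(s$lung_center_offset[1]) + s$lung_semiaxes[1] * cos(th)
  by <- s$lung_center_offset[2] + s$lung_semiaxes[2] * sin(th)
  if (max((bx / s$body_semiaxes[1])^2 + (by / s$body_semiaxes[2])^2) > 0.99)
    stop("lung ellipse must lie strictly inside the body ellipse")
  invisible(s)
}

# run expr under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# surface-arc borders (degrees from anterior midline, ipsilateral positive);
# the lateral extent grows with marker_depth_frac so the marker chord cuts
# deeper into the lung. Constants calibrated so the default cohort reproduces
# a clinically typical ipsilateral-lung V20 distribution under tangential
# fields (median ~17%, roughly 8-29% across anatomies).
breast_borders_deg <- function(spec) {
  c(
    medial = spec$breast_center_angle - 40,
    lateral = spec$breast_center_angle + 45 + 65 * spec$marker_depth_frac
  )
}

# parametric ellipse angle of a surface angle phi (deg from anterior midline)
surface_theta <- function(phi_deg, side) {
  phi <- phi_deg * pi / 180
  if (side == "left") -pi / 2 + phi else -pi / 2 - phi
}

#' Generate a phantom case
#'
#' Renders the CT volume, the ipsilateral-lung mask, the true wire-centroid
#' marker table and the (possibly jittered) annotations for a [phantom_spec()].
#' Deterministic: the seed is part of the spec.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_case` list with elements `ct` ([ct_volume()]),
#'   `lung_mask` ([lung_mask()]), `annotations` and `true_markers`
#'   ([marker_set()], 0-based slice indices), `breast_slices`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  sp <- spec$pixel_spacing
  ex <- spec$body_semiaxes[1] + spec$breast_radius + 6
  ey <- spec$body_semiaxes[2] + spec$breast_radius + 6
  ncol <- 2L * as.integer(ceiling(ex / sp[2])) + 1L
  nrow <- 2L * as.integer(ceiling(ey / sp[1])) + 1L
  n <- spec$n_slices
  x <- (seq_len(ncol) - (ncol + 1) / 2) * sp[2]
  y <- (seq_len(nrow) - (nrow + 1) / 2) * sp[1]
  xm <- matrix(x, nrow, ncol, byrow = TRUE)
  ym <- matrix(y, nrow, ncol)

  hu <- spec$hu_values
  ct_vox <- array(hu$air, dim = c(nrow, ncol, n))
  mask_vox <- array(0L, dim = c(nrow, ncol, n))

  borders <- breast_borders_deg(spec)
  th_med <- surface_theta(borders["medial"], spec$side)
  th_lat <- surface_theta(borders["lateral"], spec$side)
  side_sign <- if (spec$side == "left") 1 else -1

  # cranio-caudal taper and breast band
  u <- if (n == 1L) 0 else (seq_len(n) - (n + 1) / 2) / ((n + 1) / 2)
  taper <- sqrt(1 - 0.35 * u^2)
  breast_on <- abs(u) <= spec$breast_slice_frac & spec$breast_radius > 0

  wire_rows <- integer(0); wire_cols <- integer(0); wire_slice <- integer(0)
  wire_chan <- character(0)

  for (k in seq_len(n)) {
    A <- spec$body_semiaxes[1] * taper[k]
    B <- spec$body_semiaxes[2] * taper[k]
    rho <- sqrt((xm / A)^2 + (ym / B)^2)
    bound <- 1
    if (breast_on[k]) {
      theta <- atan2(ym / B, xm / A)
      lo <- min(th_med, th_lat); hi <- max(th_med, th_lat)
      inarc <- theta >= lo & theta <= hi
      frac <- (theta - lo) / (hi - lo)
      r_surf <- sqrt((A * cos(theta))^2 + (B * sin(theta))^2)
      bump <- ifelse(inarc, (spec$breast_radius / r_surf) * sin(pi * frac)^2, 0)
      bound <- 1 + bump
    }
    body <- rho <= bound
    sl <- matrix(hu$air, nrow, ncol)
    sl[body] <- hu$soft_tissue

    la <- spec$lung_semiaxes[1] * taper[k]
    lb <- spec$lung_semiaxes[2] * taper[k]
    ox <- spec$lung_center_offset[1] * taper[k]
    oy <- spec$lung_center_offset[2] * taper[k]
    for (sgn in c(1, -1)) {
      rho_l <- sqrt(((xm - sgn * ox) / la)^2 + ((ym - oy) / lb)^2)
      rim <- rho_l > 1.12 & rho_l <= 1.12 + 2.5 / mean(c(la, lb)) & body
      sl[rim] <- hu$bone_rim
    }
    for (sgn in c(1, -1)) {
      rho_l <- sqrt(((xm - sgn * ox) / la)^2 + ((ym - oy) / lb)^2)
      lung <- rho_l <= 1 & body
      sl[lung] <- hu$lung
      if (sgn == side_sign) mask_vox[, , k][lung] <- 1L
    }
    ct_vox[, , k] <- sl

    if (breast_on[k]) {
      for (ch in c("medial", "lateral")) {
        th <- if (ch == "medial") th_med else th_lat
        px <- A * cos(th); py <- B * sin(th)
        col <- round(px / sp[2]) + (ncol + 1) / 2
        row <- round(py / sp[1]) + (nrow + 1) / 2
        rr <- row; cc <- col
        if (spec$wire_voxels == 3L) { rr <- c(row, row, row); cc <- c(col - 1, col, col + 1) }
        wire_rows <- c(wire_rows, rr); wire_cols <- c(wire_cols, cc)
        wire_slice <- c(wire_slice, rep(k, length(rr)))
        wire_chan <- c(wire_chan, rep(ch, length(rr)))
      }
    }
  }

  if (length(wire_rows))
    ct_vox[cbind(wire_rows, wire_cols, wire_slice)] <- hu$lead_wire
  if (spec$noise_sd > 0)
    ct_vox <- ct_vox + array(stats::rnorm(length(ct_vox), 0, spec$noise_sd), dim = dim(ct_vox))
  ct_vox[ct_vox < -1024] <- -1024
  ct_vox[ct_vox > 3071] <- 3071

  ct <- ct_volume(ct_vox, sp, spec$slice_thickness)
  mask <- lung_mask(mask_vox, sp, spec$slice_thickness, side_label = spec$side)

  # true marker = centroid of the rendered wire voxel component, in mm
  true_df <- data.frame(slice = integer(0), channel = character(0),
                        x = numeric(0), y = numeric(0))
  if (length(wire_rows)) {
    key <- paste(wire_slice, wire_chan)
    for (k2 in unique(key)) {
      i <- key == k2
      mm <- voxel_to_mm(ct, mean(wire_rows[i]), mean(wire_cols[i]))
      true_df <- rbind(true_df, data.frame(
        slice = wire_slice[i][1] - 1L, channel = wire_chan[i][1],
        x = mm$x, y = mm$y
      ))
    }
  }
  true_markers <- marker_set(true_df)
  ann <- true_markers
  if (nrow(ann) > 0 && spec$annotation_jitter_sd > 0) {
    ann$x <- ann$x + stats::rnorm(nrow(ann), 0, spec$annotation_jitter_sd)
    ann$y <- ann$y + stats::rnorm(nrow(ann), 0, spec$annotation_jitter_sd)
    ann <- marker_set(as.data.frame(ann), midline_x = NULL) # keep physical identity
  }

  structure(
    list(ct = ct, lung_mask = mask, annotations = ann,
         true_markers = true_markers,
         breast_slices = which(breast_on) - 1L, spec = spec),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "<phantom_case> side %s, %d slices (%d breast-bearing), %d annotated points\n",
    x$spec$side, x$spec$n_slices, length(x$breast_slices), nrow(x$annotations)
  ))
  invisible(x)
}

#' Cohort sampling configuration
#'
#' Distributions over [phantom_spec()] fields: each varied field is a
#' `c(min, max)` uniform range, fixed fields are scalars. The `"default"`
#' preset is the study condition used throughout (1 mm pixels, 20 slices,
#' 3 mm annotation jitter); `"compact"` is the reduced-resolution condition
#' used for detector training (2 mm pixels, 8 slices, no jitter).
#'
#' @param preset `"default"` or `"compact"`.
#' @param ... overrides for individual entries.
#' @return A named list understood by [sample_cohort_specs()].
#' @export
cohort_config <- function(preset = c("default", "compact"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    body_a = c(110, 135), body_b = c(78, 95),
    lung_a = c(36, 44), lung_b = c(46, 56),
    lung_off_x = c(48, 56), lung_off_y = c(2, 8),
    breast_radius = c(18, 32), breast_center_angle = c(30, 50),
    marker_depth_frac = c(0.15, 0.85),
    side = "left", n_slices = 20, slice_thickness = 5, pixel_spacing = 1,
    breast_slice_frac = 0.6, wire_voxels = 1,
    noise_sd = 10, annotation_jitter_sd = 3
  )
  if (preset == "compact") {
    cfg$body_a <- c(95, 120); cfg$body_b <- c(70, 85)
    cfg$lung_a <- c(32, 40); cfg$lung_b <- c(40, 50)
    cfg$lung_off_x <- c(40, 48); cfg$lung_off_y <- c(2, 6)
    cfg$breast_radius <- c(16, 26)
    cfg$n_slices <- 8; cfg$pixel_spacing <- 2
    cfg$annotation_jitter_sd <- 0
  }
  utils::modifyList(cfg, list(...))
}

draw_field <- function(v) if (length(v) == 2L && is.numeric(v)) stats::runif(1, v[1], v[2]) else v

#' Sample phantom specifications for a cohort
#'
#' @param config a [cohort_config()].
#' @param n number of cases (>= 1).
#' @param seed master seed; per-case seeds are split from it.
#' @return A list of `n` [phantom_spec()] objects.
#' @export
sample_cohort_specs <- function(config = cohort_config(), n, seed = 0) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      phantom_spec(
        body_semiaxes = c(draw_field(config$body_a), draw_field(config$body_b)),
        lung_semiaxes = c(draw_field(config$lung_a), draw_field(config$lung_b)),
        lung_center_offset = c(draw_field(config$lung_off_x), draw_field(config$lung_off_y)),
        breast_radius = draw_field(config$breast_radius),
        breast_center_angle = draw_field(config$breast_center_angle),
        side = config$side, n_slices = config$n_slices,
        slice_thickness = config$slice_thickness,
        pixel_spacing = config$pixel_spacing,
        marker_depth_frac = draw_field(config$marker_depth_frac),
        breast_slice_frac = config$breast_slice_frac,
        wire_voxels = config$wire_voxels,
        noise_sd = config$noise_sd,
        annotation_jitter_sd = config$annotation_jitter_sd,
        seed = case_seeds[i]
      )
    })
  })
}

#' Sample and generate a phantom cohort
#'
#' @inheritParams sample_cohort_specs
#' @return A list of `n` `phantom_case` objects.
#' @export
sample_cohort <- function(config = cohort_config(), n, seed = 0) {
  lapply(sample_cohort_specs(config, n, seed), generate_phantom)
}

#' Threshold-based ipsilateral lung segmentation
#'
#' A deliberately simple segmenter for phantom-like HU distributions: voxels
#' within a lung HU window, taken per slice as the largest connected component
#' whose centroid lies on the requested side of the midsagittal plane.
#'
#' @param ct a [ct_volume()].
#' @param window lung HU window, default `c(-950, -400)`.
#' @param side `"left"` or `"right"`.
#' @return A [lung_mask()].
#' @export
threshold_segment_lung <- function(ct, window = c(-950, -400),
                                   side = c("left", "right")) {
  side <- match.arg(side)
  d <- dim(ct$voxels)
  out <- array(0L, dim = d)
  xs <- slice_coords(ct)$x
  sgn <- if (side == "left") 1 else -1
  for (k in seq_len(d[3])) {
    bw <- ct$voxels[, , k] >= window[1] & ct$voxels[, , k] <= window[2]
    if (!any(bw)) next
    lab <- EBImage::bwlabel(EBImage::Image(t(bw))) # EBImage is x-major
    lab <- t(EBImage::imageData(lab))
    best <- 0L; best_n <- 0L
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l, arr.ind = TRUE)
      cx <- mean(xs[idx[, 2]])
      if (sgn * cx > 0 && nrow(idx) > best_n) { best <- l; best_n <- nrow(idx) }
    }
    if (best > 0L) out[, , k][lab == best] <- 1L
  }
  if (!any(out == 1L)) stop("no lung found in the given window")
  lung_mask(out, ct$pixel_spacing, ct$slice_thickness, side_label = side)
}
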