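#' Tangential field-edge geometry for one slice
#'
#' The field edge is the line through the two lead-wire markers; the unit
#' normal perpendicular to it pointing towards the slice's lung centroid is
#' the inward normal, and the shifted edge is the marker line translated
#' `shift` mm along it (the margin moved inward per the planning-target
#' convention). The exposed side of the shifted line is the superficial side
#' — the one containing the original marker line.
#'
#' @param markers 2x2 matrix, rows (medial, lateral), cols (x, y) mm.
#' @param lung_centroid in-plane lung centroid of the slice, mm.
#' @param shift inward shift, mm (default 5).
#' @param slice_index 0-based slice index carried along.
#' @return A `field_edge` list: `point`, `direction`, `inward_normal`,
#'   `shifted_point`, `shift`, `slice_index`.
#' @export
field_edge_line <- function(markers, lung_centroid, shift = 5, slice_index = 0L) {
  p1 <- as.numeric(markers[1, ]); p2 <- as.numeric(markers[2, ])
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  if (len < 1e-9) stop("coincident markers: field edge undefined")
  u <- v / len
  n0 <- c(-u[2], u[1])
  s <- sum(n0 * (as.numeric(lung_centroid) - p1))
  if (abs(s) < 1e-9) stop("lung centroid lies on the marker line: side undefined")
  inward <- n0 * sign(s)
  structure(
    list(point = p1, direction = u, inward_normal = inward,
         shifted_point = p1 + shift * inward, shift = shift,
         slice_index = as.integer(slice_index)),
    class = "field_edge"
  )
}

# signed distance of points from the shifted edge, positive on the exposed
# (superficial) side
exposed_depth <- function(geom, x, y) {
  -((x - geom$shifted_point[1]) * geom$inward_normal[1] +
      (y - geom$shifted_point[2]) * geom$inward_normal[2])
}

#' Exposed lung area of one slice
#'
#' Counts lung pixels whose centres lie on the exposed side of the shifted
#' field edge (points exactly on the line count as exposed) times the pixel
#' area.
#'
#' @param mask_slice binary matrix `[row, col]` for the slice.
#' @param geom a [field_edge_line()] result.
#' @param pixel_spacing mm per (row, col) step.
#' @param origin in-plane mm origin of voxel (1, 1).
#' @return Area in mm^2.
#' @export
exposed_area <- function(mask_slice, geom, pixel_spacing, origin) {
  idx <- which(mask_slice == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  x <- origin[1] + (idx[, 2] - 1) * pixel_spacing[2]
  y <- origin[2] + (idx[, 1] - 1) * pixel_spacing[1]
  sum(exposed_depth(geom, x, y) >= 0) * prod(pixel_spacing[1:2])
}

#' Exposed ipsilateral-lung volume fraction (the organ feature)
#'
#' Per marker-bearing slice, the field edge through the two markers is
#' shifted `shift` mm towards the lung and the ipsilateral-lung area on the
#' exposed (superficial) side is accumulated; the sum of slice areas times
#' slice thickness is divided by the total ipsilateral-lung volume over all
#' slices. Slices with a degenerate field edge (coincident markers, centroid
#' on the line) or a missing channel contribute zero with a warning/count.
#'
#' @param mask a [lung_mask()].
#' @param markers a [marker_set()] (annotations or detections).
#' @param shift inward shift, mm (default 5).
#' @param marker_source `"labeled"` or `"detected"`, recorded in the result.
#' @param denominator `"all_slices"` (default) or `"marker_slices"`.
#' @return An `organ_feature` list: `feature` in `[0, 1]`, `per_slice`
#'   data.frame, `total_exposed_volume`, `total_lung_volume` (mm^3),
#'   `n_skipped_slices`, `marker_source`.
#' @export
compute_organ_feature <- function(mask, markers, shift = 5,
                                  marker_source = c("labeled", "detected"),
                                  denominator = c("all_slices", "marker_slices")) {
  marker_source <- match.arg(marker_source)
  denominator <- match.arg(denominator)
  stopifnot(inherits(mask, "lung_mask"))
  if (!any(mask$voxels == 1)) stop("empty lung mask")
  vox_area <- prod(mask$pixel_spacing[1:2])
  d <- dim(mask$voxels)
  slices <- marker_slices(markers)
  per_slice <- data.frame(slice = integer(0), exposed_area = numeric(0),
                          lung_area = numeric(0))
  skipped <- 0L
  cc <- slice_coords(mask)
  for (s in slices) {
    k <- s + 1L
    if (k < 1L || k > d[3]) { skipped <- skipped + 1L; next }
    msl <- mask$voxels[, , k]
    lung_area <- sum(msl == 1) * vox_area
    mp <- marker_pair(markers, s)
    if (is.null(mp) || lung_area == 0) {
      skipped <- skipped + 1L
      per_slice <- rbind(per_slice, data.frame(
        slice = s, exposed_area = 0, lung_area = lung_area
      ))
      next
    }
    idx <- which(msl == 1, arr.ind = TRUE)
    centroid <- c(mean(cc$x[idx[, 2]]), mean(cc$y[idx[, 1]]))
    geom <- tryCatch(
      field_edge_line(mp, centroid, shift = shift, slice_index = s),
      error = function(e) NULL
    )
    if (is.null(geom)) {
      warning("degenerate field edge on slice ", s, "; counted as unexposed")
      skipped <- skipped + 1L
      area <- 0
    } else {
      area <- exposed_area(msl, geom, mask$pixel_spacing, mask$origin)
    }
    per_slice <- rbind(per_slice, data.frame(
      slice = s, exposed_area = area, lung_area = lung_area
    ))
  }
  num <- sum(per_slice$exposed_area) * mask$slice_thickness
  denom_slices <- if (denominator == "all_slices") seq_len(d[3]) else
    intersect(slices + 1L, seq_len(d[3]))
  denom <- sum(mask$voxels[, , denom_slices] == 1) * vox_area * mask$slice_thickness
  structure(
    list(
      feature = if (denom > 0) num / denom else 0,
      per_slice = per_slice,
      total_exposed_volume = num,
      total_lung_volume = denom,
      n_skipped_slices = skipped,
      marker_source = marker_source,
      shift = shift
    ),
    class = "organ_feature"
  )
}

#' @export
print.organ_feature <- function(x, ...) {
  cat(sprintf(
    "<organ_feature> %.4f (%s markers, %.0f / %.0f mm^3, shift %g mm)\n",
    x$feature, x$marker_source, x$total_exposed_volume, x$total_lung_volume,
    x$shift
  ))
  invisible(x)
}

#' Serialize an organ-feature result to JSON
#' @param feat an `organ_feature`.
#' @param path output file.
#' @export
write_organ_feature <- function(feat, path) {
  jsonlite::write_json(unclass(feat), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
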