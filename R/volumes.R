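#' Spatially calibrated CT volume
#'
#' Container for an axial CT stack in Hounsfield units. Voxels are stored as a
#' 3-D array indexed `[row, col, slice]`. Patient coordinates are millimetres
#' with x along the column direction (patient left positive), y along the row
#' direction (posterior positive) and z along the slice direction; the in-plane
#' origin is the centre of the grid, so the midsagittal plane is x = 0, and
#' z = 0 at the first slice.
#'
#' @param voxels numeric 3-D array of HU values, `[row, col, slice]`.
#' @param pixel_spacing length-2 numeric, mm per (row, col) step.
#' @param slice_thickness slice spacing in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, pixel_spacing, slice_thickness) {
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  stopifnot(length(dim(voxels)) == 3L, length(pixel_spacing) == 2L)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0)
    stop("pixel_spacing and slice_thickness must be strictly positive")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop("HU values must lie within [-1024, 3071]")
  structure(
    list(
      voxels = voxels,
      pixel_spacing = as.numeric(pixel_spacing),
      slice_thickness = as.numeric(slice_thickness),
      origin = grid_origin(dim(voxels), pixel_spacing)
    ),
    class = "ct_volume"
  )
}

#' Binary ipsilateral-lung mask volume
#'
#' Shares the geometry conventions of [ct_volume()]. Values must be 0/1.
#'
#' @param voxels 3-D array of 0/1 values `[row, col, slice]`.
#' @param pixel_spacing length-2 numeric, mm per (row, col) step.
#' @param slice_thickness slice spacing in mm.
#' @param side_label `"left"` or `"right"`: which lung the mask covers.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(voxels, pixel_spacing, slice_thickness,
                      side_label = c("left", "right")) {
  side_label <- match.arg(side_label)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  stopifnot(length(dim(voxels)) == 3L)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0)
    stop("pixel_spacing and slice_thickness must be strictly positive")
  if (!all(voxels %in% c(0, 1)))
    stop("mask voxels must be binary (0/1)")
  structure(
    list(
      voxels = voxels,
      pixel_spacing = as.numeric(pixel_spacing),
      slice_thickness = as.numeric(slice_thickness),
      origin = grid_origin(dim(voxels), pixel_spacing),
      side_label = side_label
    ),
    class = "lung_mask"
  )
}

# in-plane-centred origin (mm of row 1 / col 1 / slice 1)
grid_origin <- function(dims, pixel_spacing) {
  c(
    x = -(dims[2] - 1) / 2 * pixel_spacing[2],
    y = -(dims[1] - 1) / 2 * pixel_spacing[1],
    z = 0
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, %.3g x %.3g mm pixels, %.3g mm slices, HU [%g, %g]\n",
    d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
    x$slice_thickness, min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<lung_mask> (%s) %d x %d x %d voxels, %d in mask\n",
    x$side_label, d[1], d[2], d[3], sum(x$voxels)
  ))
  invisible(x)
}

# mm coordinates of pixel centres for one slice of a volume-like object
slice_coords <- function(vol) {
  d <- dim(vol$voxels)
  list(
    x = vol$origin[["x"]] + (seq_len(d[2]) - 1) * vol$pixel_spacing[2],
    y = vol$origin[["y"]] + (seq_len(d[1]) - 1) * vol$pixel_spacing[1]
  )
}

# voxel (row, col) of the nearest pixel centre to mm point (x, y)
mm_to_voxel <- function(vol, x, y) {
  d <- dim(vol$voxels)
  col <- round((x - vol$origin[["x"]]) / vol$pixel_spacing[2]) + 1
  row <- round((y - vol$origin[["y"]]) / vol$pixel_spacing[1]) + 1
  list(row = pmin(pmax(row, 1), d[1]), col = pmin(pmax(col, 1), d[2]))
}

# mm point (x, y) of a voxel (row, col)
voxel_to_mm <- function(vol, row, col) {
  list(
    x = vol$origin[["x"]] + (col - 1) * vol$pixel_spacing[2],
    y = vol$origin[["y"]] + (row - 1) * vol$pixel_spacing[1]
  )
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$pixel_spacing - b$pixel_spacing) < tol) &&
    abs(a$slice_thickness - b$slice_thickness) < tol
}
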