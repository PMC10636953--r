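#' Simplified tangential dose model configuration
#'
#' A 2-D per-slice surrogate for the treatment planning system: on every
#' marker-bearing slice the dose is a logistic function of the signed distance
#' from the shifted field edge, `prescription / (1 + exp(-4 d / w))` with `d`
#' positive on the exposed side, so `w` approximately spans the 10-90 percent
#' penumbra falloff. Marker-free slices receive `out_of_field_dose`.
#'
#' @param prescription prescribed dose, Gy (default 50, i.e. 25 x 2 Gy).
#' @param penumbra_width logistic penumbra scale, mm.
#' @param out_of_field_dose dose on marker-free slices, Gy.
#' @param shift inward field-edge shift, mm (matches the organ feature).
#' @export
dose_config <- function(prescription = 50, penumbra_width = 6,
                        out_of_field_dose = 0, shift = 5) {
  if (prescription <= 0 || penumbra_width <= 0)
    stop("prescription and penumbra_width must be > 0")
  list(prescription = prescription, penumbra_width = penumbra_width,
       out_of_field_dose = out_of_field_dose, shift = shift)
}

#' Simulate the tangential dose grid
#'
#' @param mask a [lung_mask()] (supplies geometry and the per-slice lung
#'   centroid that orients the field edge).
#' @param markers a [marker_set()] defining the field edge per slice
#'   (typically the planning/true markers).
#' @param cfg a [dose_config()].
#' @return A `dose_grid` list: `dose` array in Gy aligned to the mask,
#'   spacing fields, and the config.
#' @export
simulate_dose <- function(mask, markers, cfg = dose_config()) {
  stopifnot(inherits(mask, "lung_mask"))
  d <- dim(mask$voxels)
  dose <- array(cfg$out_of_field_dose, dim = d)
  slices <- intersect(marker_slices(markers), seq_len(d[3]) - 1L)
  if (length(slices) == 0L) {
    warning("no annotated slices: dose grid is out-of-field everywhere")
  }
  cc <- slice_coords(mask)
  xm <- matrix(cc$x, d[1], d[2], byrow = TRUE)
  ym <- matrix(cc$y, d[1], d[2])
  for (s in slices) {
    k <- s + 1L
    msl <- mask$voxels[, , k]
    mp <- marker_pair(markers, s)
    if (is.null(mp) || !any(msl == 1)) next
    idx <- which(msl == 1, arr.ind = TRUE)
    centroid <- c(mean(cc$x[idx[, 2]]), mean(cc$y[idx[, 1]]))
    geom <- tryCatch(
      field_edge_line(mp, centroid, shift = cfg$shift, slice_index = s),
      error = function(e) NULL
    )
    if (is.null(geom)) next
    depth <- exposed_depth(geom, xm, ym)
    dose[, , k] <- cfg$prescription / (1 + exp(-4 * depth / cfg$penumbra_width))
  }
  structure(
    list(dose = dose, pixel_spacing = mask$pixel_spacing,
         slice_thickness = mask$slice_thickness, origin = mask$origin,
         cfg = cfg),
    class = "dose_grid"
  )
}

#' Dose-volume metric Vx
#'
#' Percentage of the structure's volume receiving at least `x` Gy.
#'
#' @param dose a `dose_grid` from [simulate_dose()].
#' @param structure a [lung_mask()] aligned to the dose grid.
#' @param x dose threshold(s), Gy (default 20 for V20).
#' @return Named numeric vector of percentages, one per threshold.
#' @export
compute_vx <- function(dose, structure, x = 20) {
  stopifnot(inherits(dose, "dose_grid"), inherits(structure, "lung_mask"))
  if (!identical(dim(dose$dose), dim(structure$voxels)))
    stop("dose grid and structure are not aligned")
  inside <- dose$dose[structure$voxels == 1]
  if (length(inside) == 0L) stop("empty structure")
  out <- vapply(x, function(xx) 100 * mean(inside >= xx), numeric(1))
  names(out) <- paste0("V", x)
  out
}

#' Cumulative dose-volume histogram of a structure
#'
#' @inheritParams compute_vx
#' @param breaks dose grid (Gy) at which Vx is evaluated.
#' @return data.frame with `dose_gy` and `volume_percent`.
#' @export
compute_dvh <- function(dose, structure, breaks = seq(0, 55, by = 1)) {
  data.frame(dose_gy = breaks,
             volume_percent = unname(compute_vx(dose, structure, breaks)))
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, max %.2f Gy (prescription %g Gy)\n",
              paste(dim(x$dose), collapse = " x "), max(x$dose),
              x$cfg$prescription))
  invisible(x)
}
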