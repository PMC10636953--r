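#' Write a volume to NIfTI
#'
#' CT volumes are written as floating-point HU, masks as integers. Pixel
#' spacing goes into the NIfTI header; the package's centred in-plane origin
#' convention is re-derived from the dimensions on read, so a write/read
#' round trip reproduces voxels, spacing and origin exactly.
#'
#' @param vol a [ct_volume()] or [lung_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume") || inherits(vol, "lung_mask"))
  arr <- aperm(vol$voxels, c(2, 1, 3)) # NIfTI stores x (= column) first
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vol$pixel_spacing[2], vol$pixel_spacing[1],
                           vol$slice_thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file.
#' @param as `"ct"` or `"mask"`; mask files are validated to be binary.
#' @param side_label side label attached when reading a mask.
#' @return A [ct_volume()] or [lung_mask()].
#' @export
read_volume <- function(path, as = c("ct", "mask"), side_label = "left") {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  # the reader sanitizes degenerate spacings, so validate the raw header
  hdr <- RNifti::niftiHeader(path)
  raw_pd <- hdr$pixdim[2:4]
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(raw_pd)) || any(raw_pd <= 0))
    stop("volume has missing or non-positive pixel spacing")
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(2, 1, 3))
  spacing <- c(pd[2], pd[1]) # (row, col)
  if (as == "ct") {
    ct_volume(arr, spacing, pd[3])
  } else {
    if (!all(arr %in% c(0, 1)))
      stop("mask file contains non-binary values; refusing to load as mask")
    lung_mask(arr, spacing, pd[3], side_label = side_label)
  }
}

#' Write marker annotations or detections
#'
#' JSON layout: an object keyed by 0-based slice index, each value the
#' `[[x_med, y_med], [x_lat, y_lat]]` pair in patient mm (detections carry
#' `confidence` in a parallel object). CSV layout: one row per point with
#' columns `slice, channel, x, y[, confidence]`.
#'
#' @param ms a [marker_set()].
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ms, path) {
  stopifnot(inherits(ms, "marker_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    slices <- marker_slices(ms)
    pts <- list(); conf <- list()
    for (s in slices) {
      pr <- marker_pair(ms, s)
      if (is.null(pr)) stop("every written slice must have exactly 2 points")
      pts[[as.character(s)]] <- list(unname(pr[1, ]), unname(pr[2, ]))
      if ("confidence" %in% names(ms)) {
        cc <- ms[ms$slice == s, ]
        conf[[as.character(s)]] <- cc$confidence[match(c("medial", "lateral"), cc$channel)]
      }
    }
    obj <- if (length(conf)) list(points = pts, confidence = conf) else pts
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(ms), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read marker annotations or detections
#'
#' Applies the ordering convention: per slice, the point nearer
#' `midline_x` becomes the medial channel. Rejects slices without exactly two
#' points and non-finite coordinates.
#'
#' @param path `.json` or `.csv` file written by [write_annotations()].
#' @param midline_x midsagittal x used for the medial/lateral convention.
#' @return A [marker_set()].
#' @export
read_annotations <- function(path, midline_x = 0) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    conf <- NULL
    if (is.list(obj) && all(c("points", "confidence") %in% names(obj))) {
      conf <- obj$confidence; obj <- obj$points
    }
    rows <- lapply(names(obj), function(s) {
      m <- obj[[s]]
      if (is.list(m)) m <- do.call(rbind, m)
      if (is.null(dim(m)) || nrow(m) != 2L || ncol(m) != 2L)
        stop("slice ", s, " must have exactly 2 points")
      df <- data.frame(slice = as.integer(s), channel = c("medial", "lateral"),
                       x = as.numeric(m[, 1]), y = as.numeric(m[, 2]))
      if (!is.null(conf)) df$confidence <- as.numeric(conf[[s]])
      df
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(slice = integer(0), channel = character(0),
                                      x = numeric(0), y = numeric(0))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    cnt <- table(df$slice)
    if (any(cnt != 2L))
      stop("slice(s) ", paste(names(cnt)[cnt != 2L], collapse = ", "),
           " must have exactly 2 points")
  }
  marker_set(df, midline_x = midline_x)
}

#' Study manifest
#'
#' A manifest maps case ids to file paths (ct, lung_mask, annotations, and
#' optionally detections/dose) plus a cohort split label. All referenced
#' paths must exist at load time and split labels are disjoint by
#' construction (one label per case).
#'
#' @param df data.frame with columns `id`, `split`
#'   (train/validation/test), and path columns.
#' @param path JSON file.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the validated
#'   data.frame.
#' @export
write_manifest <- function(df, path) {
  stopifnot(all(c("id", "split") %in% names(df)))
  if (anyDuplicated(df$id)) stop("case ids must be unique")
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("id", "split") %in% names(df)))
  pcols <- setdiff(names(df), c("id", "split"))
  for (cn in pcols) {
    missing <- !vapply(df[[cn]], function(p) is.na(p) || file.exists(p), logical(1))
    if (any(missing))
      stop("missing file(s) referenced by manifest column '", cn, "': ",
           paste(df[[cn]][missing], collapse = ", "))
  }
  df
}
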