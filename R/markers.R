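#' Per-slice lead-wire marker set
#'
#' A marker set holds the two lead-wire points of each breast-bearing axial
#' slice in patient millimetres, ordered by convention: the *medial* point is
#' the one nearer the midsagittal plane (smaller `|x - midline_x|`), the
#' *lateral* point the other. Detections carry an additional `confidence`
#' column; ground-truth annotations do not.
#'
#' @param df data.frame with columns `slice` (0-based slice index), `channel`
#'   (`"medial"`/`"lateral"`), `x`, `y` (mm) and optionally `confidence`.
#' @param midline_x x-coordinate of the midsagittal plane used to (re)apply the
#'   ordering convention; `NULL` keeps the given channels untouched.
#' @return A `marker_set`: the validated, convention-ordered data.frame.
#' @export
marker_set <- function(df, midline_x = 0) {
  req <- c("slice", "channel", "x", "y")
  if (!all(req %in% names(df))) stop("marker set needs columns slice, channel, x, y")
  df <- as.data.frame(df)
  if (nrow(df) > 0) {
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      stop("marker coordinates must be finite")
    df$slice <- as.integer(df$slice)
    df$channel <- as.character(df$channel)
    if (!all(df$channel %in% c("medial", "lateral")))
      stop("channel must be 'medial' or 'lateral'")
    if (!is.null(midline_x)) df <- order_markers(df, midline_x)
    if (anyDuplicated(df[c("slice", "channel")]))
      stop("at most one point per channel per slice")
    df <- df[order(df$slice, match(df$channel, c("medial", "lateral"))), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("marker_set", "data.frame")
  df
}

# reassign channels so the point nearer midline_x is medial (per slice)
order_markers <- function(df, midline_x = 0) {
  for (s in unique(df$slice)) {
    i <- which(df$slice == s)
    if (length(i) == 2L) {
      med_first <- abs(df$x[i[1]] - midline_x) <= abs(df$x[i[2]] - midline_x)
      df$channel[i] <- if (med_first) c("medial", "lateral") else c("lateral", "medial")
    }
  }
  df
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf(
    "<marker_set> %d points on %d slice(s)%s\n",
    nrow(x), length(unique(x$slice)),
    if ("confidence" %in% names(x)) " (with confidences)" else ""
  ))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# the (medial, lateral) pair of one slice as a 2x2 matrix (rows = points),
# or NULL if either channel is missing
marker_pair <- function(ms, slice) {
  med <- ms[ms$slice == slice & ms$channel == "medial", , drop = FALSE]
  lat <- ms[ms$slice == slice & ms$channel == "lateral", , drop = FALSE]
  if (nrow(med) != 1L || nrow(lat) != 1L) return(NULL)
  rbind(medial = c(med$x, med$y), lateral = c(lat$x, lat$y))
}

marker_slices <- function(ms) sort(unique(ms$slice))
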