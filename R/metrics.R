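#' Match predicted to ground-truth markers at a distance tolerance
#'
#' Matching is channel-respecting by default: a prediction can only match the
#' ground-truth point of the same slice and channel, and does so iff their
#' in-plane Euclidean distance is within `tolerance` mm. Unmatched predictions
#' are false positives, unmatched ground truths false negatives. The
#' `"hungarian"` mode instead assigns predictions to ground truths per slice
#' ignoring channel labels, minimizing total distance.
#'
#' @param pred,gt [marker_set()] objects in the same patient-mm frame.
#' @param tolerance match radius, mm.
#' @param mode `"channel"` (default) or `"hungarian"`.
#' @return List with data.frames `tp` (with `dist`), `fp`, `fn`.
#' @export
match_predictions <- function(pred, gt, tolerance, mode = c("channel", "hungarian")) {
  mode <- match.arg(mode)
  pred <- as.data.frame(pred); gt <- as.data.frame(gt)
  tp <- list(); fp <- list(); fn <- list()
  slices <- union(pred$slice, gt$slice)
  for (s in slices) {
    p <- pred[pred$slice == s, , drop = FALSE]
    g <- gt[gt$slice == s, , drop = FALSE]
    if (mode == "channel") {
      pairs <- merge(p, g, by = c("slice", "channel"),
                     suffixes = c("_p", "_g"))
      pairs$dist <- sqrt((pairs$x_p - pairs$x_g)^2 + (pairs$y_p - pairs$y_g)^2)
      ok <- pairs$dist <= tolerance
      tp[[length(tp) + 1L]] <- pairs[ok, c("slice", "channel", "dist")]
      fp[[length(fp) + 1L]] <- rbind(
        p[!p$channel %in% g$channel, c("slice", "channel")],
        pairs[!ok, c("slice", "channel")]
      )
      fn[[length(fn) + 1L]] <- rbind(
        g[!g$channel %in% p$channel, c("slice", "channel")],
        pairs[!ok, c("slice", "channel")]
      )
    } else {
      np <- nrow(p); ng <- nrow(g)
      best <- NULL; best_cost <- Inf
      k <- min(np, ng)
      if (k > 0) {
        pidx <- utils::combn(np, k, simplify = FALSE)
        for (ps in pidx) for (gs in combinat_perms(ng, k)) {
          d <- sqrt((p$x[ps] - g$x[gs])^2 + (p$y[ps] - g$y[gs])^2)
          cost <- sum(pmin(d, tolerance * 2)) # soft cap keeps far pairs losable
          if (cost < best_cost) { best_cost <- cost; best <- list(ps = ps, gs = gs, d = d) }
        }
      }
      matched_p <- logical(np); matched_g <- logical(ng)
      if (!is.null(best)) {
        ok <- best$d <= tolerance
        matched_p[best$ps[ok]] <- TRUE; matched_g[best$gs[ok]] <- TRUE
        tp[[length(tp) + 1L]] <- data.frame(
          slice = s, channel = g$channel[best$gs[ok]], dist = best$d[ok]
        )
      }
      fp[[length(fp) + 1L]] <- p[!matched_p, c("slice", "channel")]
      fn[[length(fn) + 1L]] <- g[!matched_g, c("slice", "channel")]
    }
  }
  empty <- data.frame(slice = integer(0), channel = character(0))
  list(
    tp = if (length(tp)) do.call(rbind, tp) else cbind(empty, dist = numeric(0)),
    fp = if (length(fp)) do.call(rbind, fp) else empty,
    fn = if (length(fn)) do.call(rbind, fn) else empty
  )
}

# ordered k-subsets of 1..n (assignments for the small per-slice problems)
combinat_perms <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) { out[[length(out) + 1L]] <<- prefix; return() }
    for (i in remaining) rec(c(prefix, i), setdiff(remaining, i))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Detection evaluation report
#'
#' Localization distance statistics and average precision/recall at distance
#' tolerances. The distance pool is every same-channel (prediction, ground
#' truth) pair where both exist, irrespective of tolerance, so the distance
#' summary does not depend on the tolerance grid. `AP_t = TP/(TP+FP)` and
#' `AR_t = TP/(TP+FN)` at each tolerance; the sample (n-1) standard deviation
#' is reported. Undefined quantities (no pairs, or 0/0 ratios) are `NA`.
#'
#' @param pred,gt [marker_set()] objects in the same frame.
#' @param tolerances tolerance grid in mm (default `c(5, 10)`).
#' @param mode matching mode, see [match_predictions()].
#' @return A `detection_report` list: `dist_mean`, `dist_sd`, `n_pairs`,
#'   per-tolerance `ap`, `ar`, `tp`, `fp`, `fn`, plus point counts.
#' @export
detection_report <- function(pred, gt, tolerances = c(5, 10),
                             mode = c("channel", "hungarian")) {
  mode <- match.arg(mode)
  pg <- merge(as.data.frame(pred), as.data.frame(gt),
              by = c("slice", "channel"), suffixes = c("_p", "_g"))
  dists <- sqrt((pg$x_p - pg$x_g)^2 + (pg$y_p - pg$y_g)^2)
  per_tol <- lapply(tolerances, function(tol) {
    m <- match_predictions(pred, gt, tol, mode = mode)
    tp <- nrow(m$tp); fp <- nrow(m$fp); fn <- nrow(m$fn)
    list(
      tolerance = tol, tp = tp, fp = fp, fn = fn,
      ap = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      ar = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    )
  })
  names(per_tol) <- paste0("tol_", tolerances)
  structure(
    list(
      dist_mean = if (length(dists)) mean(dists) else NA_real_,
      dist_sd = if (length(dists) > 1) stats::sd(dists) else NA_real_,
      n_pairs = length(dists),
      per_tolerance = per_tol,
      n_slices = length(union(unique(pred$slice), unique(gt$slice))),
      n_gt_points = nrow(gt), n_pred_points = nrow(pred)
    ),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> dist %.3f +/- %.3f mm over %d pairs\n",
              x$dist_mean, x$dist_sd, x$n_pairs))
  for (t in x$per_tolerance)
    cat(sprintf("  @%g mm: AP %.3f  AR %.3f  (TP %d FP %d FN %d)\n",
                t$tolerance, t$ap, t$ar, t$tp, t$fp, t$fn))
  invisible(x)
}

#' Serialize a detection report to JSON
#' @param report a `detection_report`.
#' @param path output file.
#' @export
write_detection_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
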