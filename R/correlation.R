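#' Pearson correlation with interpretation band
#'
#' Product-moment correlation with a two-sided t-test p-value
#' (`t = r sqrt((n-2)/(1-r^2))`, n-2 df) and a Fisher-z 95% confidence
#' interval, plus the strength band used for reporting: `|r|` in `[0, 0.3)`
#' is weak, `[0.3, 0.5)` moderate, `[0.5, 1]` correlated.
#'
#' @param x,y numeric vectors of equal length, n >= 3, both non-constant.
#' @return A `correlation_result` list: `r`, `n`, `p`, `ci95`,
#'   `interpretation`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3 for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  r <- unname(ct$estimate)
  # Fisher z interval needs n > 3; at n = 3 the interval is vacuous
  ci <- if (is.null(ct$conf.int)) c(-1, 1) else as.numeric(ct$conf.int)
  structure(
    list(r = r, n = length(x), p = ct$p.value,
         ci95 = ci,
         interpretation = interpret_correlation(r)),
    class = "correlation_result"
  )
}

#' Correlation strength band
#'
#' @param r correlation coefficient, `|r| <= 1`.
#' @return `"weak"`, `"moderate"` or `"correlated"`.
#' @export
interpret_correlation <- function(r) {
  if (!is.finite(r) || abs(r) > 1) stop("|r| must be <= 1")
  a <- abs(r)
  if (a < 0.3) "weak" else if (a < 0.5) "moderate" else "correlated"
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.3f (n = %d, p = %.3g, 95%% CI %.3f..%.3f): %s\n",
              x$r, x$n, x$p, x$ci95[1], x$ci95[2], x$interpretation))
  invisible(x)
}

#' Paired comparison of two feature vectors
#'
#' Two-sided paired t-test on the per-case differences. Zero-variance
#' differences are handled explicitly: all-zero differences give `t = 0,
#' p = 1`; constant nonzero differences give `p = 0` with a warning.
#'
#' @param a,b numeric vectors of equal length, n >= 2.
#' @return List with `statistic`, `p`, `mean_difference`, `n`.
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need n >= 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(statistic = 0, p = 1, mean_difference = 0,
                                 n = length(d)))
    warning("constant nonzero differences: p reported as limit 0")
    return(list(statistic = Inf * sign(mean(d)), p = 0,
                mean_difference = mean(d), n = length(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       mean_difference = unname(tt$estimate), n = length(d))
}

#' Cohort correlation report
#'
#' Correlates the labeled-marker and detected-marker organ features with
#' lung V20 on the same complete-case set and compares the two feature
#' vectors pairwise.
#'
#' @param table data.frame with columns `id`, `feature_labeled`,
#'   `feature_detected`, `v20`.
#' @return A `cohort_report` list: `labeled` and `detected`
#'   [pearson_cor()] results, `paired` ([paired_compare()]), `n_cases`,
#'   `n_dropped`, and the case `table`.
#' @export
cohort_analysis <- function(table) {
  req <- c("id", "feature_labeled", "feature_detected", "v20")
  if (!all(req %in% names(table)))
    stop("table needs columns ", paste(req, collapse = ", "))
  complete <- stats::complete.cases(table[req])
  if (any(!complete))
    message(sum(!complete), " case(s) with missing values dropped")
  tb <- table[complete, , drop = FALSE]
  if (nrow(tb) < 3L) stop("need >= 3 complete cases")
  structure(
    list(
      labeled = pearson_cor(tb$feature_labeled, tb$v20),
      detected = pearson_cor(tb$feature_detected, tb$v20),
      paired = paired_compare(tb$feature_labeled, tb$feature_detected),
      n_cases = nrow(tb), n_dropped = sum(!complete),
      table = tb
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d cases\n", x$n_cases))
  cat(sprintf("  feature (labeled markers)  vs V20: r = %.3f, p = %.3g (%s)\n",
              x$labeled$r, x$labeled$p, x$labeled$interpretation))
  cat(sprintf("  feature (detected markers) vs V20: r = %.3f, p = %.3g (%s)\n",
              x$detected$r, x$detected$p, x$detected$interpretation))
  cat(sprintf("  labeled vs detected features: paired t = %.3f, p = %.3g\n",
              x$paired$statistic, x$paired$p))
  invisible(x)
}

#' Serialize a cohort report
#' @param report a `cohort_report`.
#' @param path output JSON file.
#' @export
write_cohort_report <- function(report, path) {
  obj <- unclass(report)
  obj$labeled <- unclass(obj$labeled)
  obj$detected <- unclass(obj$detected)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
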