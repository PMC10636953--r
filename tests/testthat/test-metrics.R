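test_that("perfect detections give zero distance and perfect AP/AR", {
  gt <- random_marker_set(6, p_missing = 0, seed = 3)
  rep <- detection_report(gt, gt)
  expect_equal(rep$dist_mean, 0)
  expect_equal(rep$dist_sd, 0)
  for (t in rep$per_tolerance) {
    expect_equal(t$ap, 1); expect_equal(t$ar, 1)
    expect_equal(t$fp, 0); expect_equal(t$fn, 0)
  }
})

test_that("a uniform 7 mm displacement flips the 5 mm and 10 mm tolerances", {
  gt <- random_marker_set(5, p_missing = 0, seed = 4)
  pred <- gt
  pred$x <- pred$x + 7 / sqrt(2)
  pred$y <- pred$y + 7 / sqrt(2)
  rep <- detection_report(pred, gt)
  expect_equal(rep$dist_mean, 7)
  expect_equal(rep$per_tolerance$tol_5$ap, 0)
  expect_equal(rep$per_tolerance$tol_5$ar, 0)
  expect_equal(rep$per_tolerance$tol_10$ap, 1)
  expect_equal(rep$per_tolerance$tol_10$ar, 1)
})

test_that("hand-enumerated mixed case: distances 1, 2, 6 mm plus a missing channel", {
  gt <- marker_set(data.frame(
    slice = c(0, 0, 1, 1), channel = rep(c("medial", "lateral"), 2),
    x = c(0, 50, 0, 50), y = c(0, 0, 10, 10)
  ), midline_x = NULL)
  pred <- marker_set(data.frame(
    slice = c(0, 0, 1), channel = c("medial", "lateral", "medial"),
    x = c(1, 52, 6), y = c(0, 0, 10) # distances 1, 2, 6; slice-1 lateral missing
  ), midline_x = NULL)
  m <- match_predictions(pred, gt, tolerance = 5)
  expect_equal(nrow(m$tp), 2)
  expect_equal(nrow(m$fp), 1)
  expect_equal(nrow(m$fn), 2)
  rep <- detection_report(pred, gt)
  expect_equal(rep$dist_mean, 3)                  # mean of {1, 2, 6}
  expect_equal(rep$dist_sd, sqrt(7))              # sample SD 2.6458
  expect_equal(rep$per_tolerance$tol_5$tp +
                 rep$per_tolerance$tol_5$fn, nrow(gt))
  expect_equal(rep$per_tolerance$tol_10$tp +
                 rep$per_tolerance$tol_10$fp, nrow(pred))
})

test_that("metrics honour their contracts on randomized inputs", {
  for (seed in 1:8) {
    gt <- random_marker_set(6, p_missing = 0.25, seed = seed)
    pred <- random_marker_set(6, p_missing = 0.25, jitter = 6, seed = seed + 100)
    rep <- detection_report(pred, gt)
    t5 <- rep$per_tolerance$tol_5; t10 <- rep$per_tolerance$tol_10
    for (t in list(t5, t10)) {
      if (!is.na(t$ap)) expect_true(t$ap >= 0 && t$ap <= 1)
      if (!is.na(t$ar)) expect_true(t$ar >= 0 && t$ar <= 1)
      expect_equal(t$tp + t$fn, nrow(gt))
      expect_equal(t$tp + t$fp, nrow(pred))
    }
    expect_gte(t10$tp, t5$tp)
    if (!is.na(t5$ap)) expect_gte(t10$ap, t5$ap)
    if (!is.na(t5$ar)) expect_gte(t10$ar, t5$ar)
    # agreement with the independent brute-force matcher
    for (tol in c(3, 5, 10)) {
      m <- match_predictions(pred, gt, tol)
      bc <- brute_match_counts(pred, gt, tol)
      expect_equal(nrow(m$tp), unname(bc["tp"]))
      expect_equal(nrow(m$fp), unname(bc["fp"]))
      expect_equal(nrow(m$fn), unname(bc["fn"]))
    }
  }
})

test_that("metrics are invariant under a rigid transform of both point sets", {
  gt <- random_marker_set(5, p_missing = 0.2, seed = 9)
  pred <- random_marker_set(5, p_missing = 0.2, jitter = 5, seed = 10)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid <- function(ms) {
    xy <- cbind(ms$x, ms$y) %*% t(R)
    ms$x <- xy[, 1] + 13.5; ms$y <- xy[, 2] - 7.25
    ms
  }
  a <- detection_report(pred, gt)
  b <- detection_report(rigid(pred), rigid(gt))
  expect_equal(a$dist_mean, b$dist_mean)
  expect_equal(a$dist_sd, b$dist_sd)
  expect_equal(a$per_tolerance, b$per_tolerance)
})

test_that("an empty detector yields flagged undefined distance and AP", {
  gt <- random_marker_set(4, p_missing = 0, seed = 2)
  empty <- marker_set(data.frame(slice = integer(0), channel = character(0),
                                 x = numeric(0), y = numeric(0)))
  rep <- detection_report(empty, gt)
  expect_true(is.na(rep$dist_mean))
  expect_true(is.na(rep$per_tolerance$tol_5$ap)) # 0/0
  expect_equal(rep$per_tolerance$tol_5$ar, 0)
})

test_that("hungarian matching recovers channel-swapped detections", {
  gt <- marker_set(data.frame(
    slice = 0, channel = c("medial", "lateral"), x = c(10, 90), y = c(0, 0)
  ), midline_x = NULL)
  swapped <- marker_set(data.frame(
    slice = 0, channel = c("lateral", "medial"), x = c(10.5, 89), y = c(0, 0)
  ), midline_x = NULL)
  strict <- match_predictions(swapped, gt, 5)
  expect_equal(nrow(strict$tp), 0) # channel-respecting: both wrong
  loose <- match_predictions(swapped, gt, 5, mode = "hungarian")
  expect_equal(nrow(loose$tp), 2)
})
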