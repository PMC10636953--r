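test_that("field edge geometry matches the axis-aligned worked cases", {
  mk <- rbind(c(0, 0), c(100, 0))
  g1 <- field_edge_line(mk, c(50, 80), shift = 5)
  expect_equal(g1$inward_normal, c(0, 1))
  expect_equal(g1$shifted_point[2], 5)
  g2 <- field_edge_line(mk, c(50, -80), shift = 5)
  expect_equal(g2$inward_normal, c(0, -1))
  expect_equal(g2$shifted_point[2], -5)
  expect_error(field_edge_line(rbind(c(0, 0), c(0, 0)), c(1, 1)), "coincident")
  expect_error(field_edge_line(mk, c(50, 0)), "on the marker line")
})

test_that("exposed area counts pixel centres on the superficial side", {
  # 20 x 10 mm rectangular lung at 1 mm spacing, origin centred on the grid
  mask <- array(0L, c(30, 30, 1))
  mask[11:20, 6:25, 1] <- 1L  # rows = y, cols = x
  mk <- lung_mask(mask, c(1, 1), 5)
  geom_all <- field_edge_line(rbind(c(-10, -14), c(10, -14)), c(0, 1), shift = 5)
  expect_equal(exposed_area(mask[, , 1], geom_all, c(1, 1), mk$origin), 0)
  # line far on the other side: everything exposed
  geom_none <- field_edge_line(rbind(c(-10, 20), c(10, 20)), c(0, 100), shift = 5)
  expect_equal(exposed_area(mask[, , 1], geom_none, c(1, 1), mk$origin), 200)
  # bisecting case against explicit per-pixel counting
  geom_half <- field_edge_line(rbind(c(-10, -5), c(10, -5)), c(0, 10), shift = 5)
  # shifted line at y = 0; exposed side is y <= 0
  idx <- which(mask[, , 1] == 1, arr.ind = TRUE)
  ys <- mk$origin[["y"]] + (idx[, 1] - 1) * 1
  expect_equal(exposed_area(mask[, , 1], geom_half, c(1, 1), mk$origin),
               sum(ys <= 0))
})

test_that("feature hits its boundary values", {
  mask <- array(0L, c(20, 20, 2))
  mask[9:10, 5:15, ] <- 1L  # thin lung slab near y = 0
  mk <- lung_mask(mask, c(1, 1), 5)
  ms0 <- marker_set(data.frame(slice = integer(0), channel = character(0),
                               x = numeric(0), y = numeric(0)))
  expect_equal(compute_organ_feature(mk, ms0)$feature, 0)
  # markers on both slices, whole lung within 5 mm of the marker line
  ys <- tangentfeat:::slice_coords(mk)$y[9:10] # lung rows in mm
  ms <- marker_set(data.frame(
    slice = c(0, 0, 1, 1), channel = rep(c("medial", "lateral"), 2),
    x = c(-8, 8, -8, 8), y = rep(min(ys) - 1, 4)
  ), midline_x = NULL)
  f <- compute_organ_feature(mk, ms, shift = 5)
  expect_equal(f$feature, 1)
  expect_error(compute_organ_feature(lung_mask(array(0L, c(4, 4, 1)), c(1, 1), 5), ms),
               "empty lung mask")
})

test_that("feature equals the brute-force per-voxel oracle on phantoms", {
  for (seed in 1:5) {
    p <- generate_phantom(tiny_spec(seed = seed,
                                    marker_depth_frac = 0.2 * seed))
    f <- compute_organ_feature(p$lung_mask, p$annotations, shift = 5)
    expect_equal(f$feature, feature_oracle(p$lung_mask, p$annotations, 5),
                 tolerance = 1e-12)
  }
})

test_that("feature is non-decreasing in the margin shift", {
  p <- generate_phantom(tiny_spec(seed = 11, marker_depth_frac = 0.6))
  feats <- vapply(c(0, 2.5, 5, 10, 20), function(s)
    compute_organ_feature(p$lung_mask, p$annotations, shift = s)$feature,
    numeric(1))
  expect_true(all(diff(feats) >= 0))
  expect_gt(feats[5], feats[1])
})

test_that("feature is stable under resolution refinement", {
  base <- list(seed = 5, marker_depth_frac = 0.7)
  f2 <- compute_organ_feature(
    generate_phantom(do.call(tiny_spec, c(base, list(pixel_spacing = 2))))$lung_mask,
    generate_phantom(do.call(tiny_spec, c(base, list(pixel_spacing = 2))))$annotations
  )$feature
  f1 <- compute_organ_feature(
    generate_phantom(do.call(tiny_spec, c(base, list(pixel_spacing = 1))))$lung_mask,
    generate_phantom(do.call(tiny_spec, c(base, list(pixel_spacing = 1))))$annotations
  )$feature
  expect_lt(abs(f1 - f2) / f1, 0.05)
})

test_that("a 90-degree in-plane rotation leaves the exposed area unchanged", {
  p <- generate_phantom(tiny_spec(seed = 8, marker_depth_frac = 0.8))
  k <- p$breast_slices[2] + 1L
  msl <- p$lung_mask$voxels[, , k]
  mp <- marker_pair(p$annotations, k - 1L)
  idx <- which(msl == 1, arr.ind = TRUE)
  cc <- tangentfeat:::slice_coords(p$lung_mask)
  centroid <- c(mean(cc$x[idx[, 2]]), mean(cc$y[idx[, 1]]))
  a0 <- exposed_area(msl, field_edge_line(mp, centroid, 5),
                     p$lung_mask$pixel_spacing, p$lung_mask$origin)
  # rotate 90 deg: (x, y) -> (-y, x); grid transposes, mask rotates with it
  rot_msl <- t(msl)[, nrow(msl):1]
  rot <- function(pt) c(-pt[2], pt[1])
  rot_geom <- field_edge_line(rbind(rot(mp[1, ]), rot(mp[2, ])), rot(centroid), 5)
  rmk <- lung_mask(array(rot_msl, c(nrow(rot_msl), ncol(rot_msl), 1)),
                   rev(p$lung_mask$pixel_spacing), p$lung_mask$slice_thickness)
  a90 <- exposed_area(rot_msl, rot_geom, rmk$pixel_spacing, rmk$origin)
  expect_equal(a90, a0)
})
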