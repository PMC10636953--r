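test_that("phantom generation is deterministic for a fixed spec", {
  s <- tiny_spec(noise_sd = 10, annotation_jitter_sd = 2)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$lung_mask$voxels, b$lung_mask$voxels)
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))
})

test_that("jitter-free annotations coincide with wire voxel-component centroids", {
  for (wv in c(1L, 3L)) {
    p <- generate_phantom(tiny_spec(wire_voxels = wv))
    det <- classical_detect(p$ct)
    expect_gt(nrow(p$annotations), 0)
    m <- merge(as.data.frame(p$annotations), as.data.frame(det),
               by = c("slice", "channel"))
    expect_equal(nrow(m), nrow(p$annotations))
    expect_equal(m$x.x, m$x.y, tolerance = 1e-12)
    expect_equal(m$y.x, m$y.y, tolerance = 1e-12)
  }
})

test_that("degenerate anatomy: no breast means no annotated slices", {
  p <- generate_phantom(tiny_spec(breast_radius = 0))
  expect_equal(nrow(p$annotations), 0)
  expect_equal(length(p$breast_slices), 0)
})

test_that("invalid specs are rejected", {
  expect_error(tiny_spec(lung_center_offset = c(70, 4)), "inside the body")
  expect_error(tiny_spec(n_slices = 0), "n_slices")
  expect_error(tiny_spec(pixel_spacing = 0), "positive")
  expect_error(tiny_spec(marker_depth_frac = 1.2), "marker_depth_frac")
})

test_that("true markers lie on the body surface contour", {
  # in a noise-free phantom a surface point has both air and soft tissue
  # within its immediate in-plane neighbourhood
  p <- generate_phantom(tiny_spec())
  hu <- p$spec$hu_values
  for (i in seq_len(nrow(p$true_markers))) {
    r <- p$true_markers[i, ]
    v <- tangentfeat:::mm_to_voxel(p$ct, r$x, r$y)
    nb <- p$ct$voxels[
      max(1, v$row - 2):min(dim(p$ct$voxels)[1], v$row + 2),
      max(1, v$col - 2):min(dim(p$ct$voxels)[2], v$col + 2),
      r$slice + 1L
    ]
    expect_true(any(nb == hu$air), label = "air adjacent to marker")
    expect_true(any(nb == hu$soft_tissue), label = "soft tissue adjacent to marker")
  }
})

test_that("lung mask lies on the requested side of the midsagittal plane", {
  for (side in c("left", "right")) {
    p <- generate_phantom(tiny_spec(side = side))
    idx <- which(p$lung_mask$voxels == 1, arr.ind = TRUE)
    xs <- p$lung_mask$origin[["x"]] + (idx[, 2] - 1) * p$lung_mask$pixel_spacing[2]
    expect_true(if (side == "left") mean(xs) > 0 else mean(xs) < 0)
  }
})

test_that("cohort sampling is reproducible and spans the configured ranges", {
  expect_error(sample_cohort_specs(cohort_config(), 0, seed = 1), "n must be")
  a <- sample_cohort(cohort_config("compact"), 3, seed = 7)
  b <- sample_cohort(cohort_config("compact"), 3, seed = 7)
  expect_identical(lapply(a, function(p) p$ct$voxels),
                   lapply(b, function(p) p$ct$voxels))
  cfg <- cohort_config()
  specs <- sample_cohort_specs(cfg, 100, seed = 5)
  depths <- vapply(specs, `[[`, numeric(1), "marker_depth_frac")
  expect_gte(min(depths), cfg$marker_depth_frac[1])
  expect_lte(max(depths), cfg$marker_depth_frac[2])
  # the draw should cover most of the configured range
  expect_lt(min(depths), cfg$marker_depth_frac[1] + 0.1)
  expect_gt(max(depths), cfg$marker_depth_frac[2] - 0.1)
  # zero-variance config: identical anatomy apart from seeds
  czv <- cohort_config("compact",
                       body_a = 100, body_b = 75, lung_a = 34, lung_b = 42,
                       lung_off_x = 42, lung_off_y = 4, breast_radius = 20,
                       breast_center_angle = 40, marker_depth_frac = 0.5)
  szv <- sample_cohort_specs(czv, 3, seed = 2)
  expect_equal(szv[[1]]$body_semiaxes, szv[[2]]$body_semiaxes)
  expect_equal(szv[[1]]$marker_depth_frac, szv[[3]]$marker_depth_frac)
  expect_false(szv[[1]]$seed == szv[[2]]$seed)
})

test_that("threshold segmentation recovers the ground-truth lung", {
  p <- generate_phantom(tiny_spec(noise_sd = 0))
  seg <- threshold_segment_lung(p$ct, side = "left")
  expect_identical(seg$voxels == 1, p$lung_mask$voxels == 1)
  pj <- generate_phantom(phantom_spec(seed = 3)) # default study condition
  segj <- threshold_segment_lung(pj$ct, side = "left")
  dice <- 2 * sum(segj$voxels & pj$lung_mask$voxels) /
    (sum(segj$voxels) + sum(pj$lung_mask$voxels))
  expect_gte(dice, 0.99)
  flat <- ct_volume(array(40, dim = c(12, 12, 2)), c(1, 1), 5)
  expect_error(threshold_segment_lung(flat), "no lung found")
})
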