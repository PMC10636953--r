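test_that("clip_normalize maps the HU window onto [0, 1]", {
  cfg <- preprocess_config()
  expect_equal(clip_normalize(array(-140, c(1, 1, 1)), cfg)[1], 0)
  expect_equal(clip_normalize(array(210, c(1, 1, 1)), cfg)[1], 1)
  expect_equal(clip_normalize(array(35, c(1, 1, 1)), cfg)[1], 0.5)
  expect_equal(clip_normalize(array(-1000, c(1, 1, 1)), cfg)[1], 0)
  expect_equal(clip_normalize(array(3000, c(1, 1, 1)), cfg)[1], 1)
  # monotone, range-bounded, and stable on window endpoints
  v <- array(seq(-1024, 3071, length.out = 64), c(4, 4, 4))
  nv <- clip_normalize(v, cfg)
  expect_true(all(diff(as.vector(nv)) >= 0))
  expect_true(all(nv >= 0 & nv <= 1))
  hu_again <- nv * (210 - (-140)) + (-140)
  expect_equal(clip_normalize(array(hu_again, dim(v)), cfg), nv)
})

test_that("slab extraction replicates edges", {
  nv <- array(seq_len(2 * 2 * 4), c(2, 2, 4))
  expect_equal(make_slab(nv, 3)[, , 1], nv[, , 2])
  expect_equal(make_slab(nv, 3)[, , 3], nv[, , 4])
  expect_equal(make_slab(nv, 1)[, , 1], nv[, , 1]) # replicated first slice
  expect_equal(make_slab(nv, 1)[, , 2], nv[, , 1])
  single <- array(1:4, c(2, 2, 1))
  sl <- make_slab(single, 1)
  expect_equal(sl[, , 1], sl[, , 2])
  expect_equal(sl[, , 2], sl[, , 3])
  expect_error(make_slab(nv, 5), "outside")
})

test_that("heatmap targets are unit-peak Gaussians of the stated width", {
  geom <- ct_volume(array(0, c(21, 21, 1)), c(1, 1), 5)
  mk <- rbind(medial = c(-3, 2), lateral = c(5, -4))
  hm <- make_heatmap_target(mk, geom, heatmap_spec(sigma = 5))
  for (ch in 1:2) {
    pk <- which(hm[, , ch] == max(hm[, , ch]), arr.ind = TRUE)
    mm <- tangentfeat:::voxel_to_mm(geom, pk[1], pk[2])
    expect_equal(c(mm$x, mm$y), unname(mk[ch, ]))
    expect_equal(max(hm[, , ch]), 1)
  }
  # value at one sigma from the peak
  v5 <- tangentfeat:::mm_to_voxel(geom, -3 + 5, 2)
  expect_equal(hm[v5$row, v5$col, 1], exp(-0.5))
  expect_equal(make_heatmap_target(NULL, geom), array(0, c(21, 21, 2)))
  expect_error(make_heatmap_target(rbind(c(99, 0), c(0, 0)), geom), "bounds")
})

test_that("heatmap decoding takes the per-channel argmax with tie-breaks", {
  geom <- ct_volume(array(0, c(10, 12, 1)), c(2, 2), 5)
  hm <- array(0, c(10, 12, 2))
  hm[4, 7, 1] <- 0.8
  hm[9, 2, 2] <- 0.6
  det <- decode_heatmaps(hm, geom, slice = 3L)
  expect_equal(nrow(det), 2)
  med <- det[det$channel == "medial", ]
  mm <- tangentfeat:::voxel_to_mm(geom, 4, 7)
  expect_equal(c(med$x, med$y), c(mm$x, mm$y))
  expect_equal(med$confidence, 0.8)
  expect_equal(unique(det$slice), 3L)
  # tie: lowest row, then lowest column
  hm2 <- array(0, c(10, 12, 2))
  hm2[c(5, 7), c(3), 1] <- 0.5
  hm2[5, c(3, 8), 2] <- 0.5
  det2 <- decode_heatmaps(hm2, geom)
  expect_equal(tangentfeat:::mm_to_voxel(geom, det2$x[1], det2$y[1])$row, 5)
  expect_equal(tangentfeat:::mm_to_voxel(geom, det2$x[2], det2$y[2])$col, 3)
  # sub-threshold channels emit nothing
  expect_equal(nrow(decode_heatmaps(array(0.05, c(10, 12, 2)), geom)), 0)
})

test_that("decode recovers encoded markers to within half a pixel diagonal", {
  geom <- ct_volume(array(0, c(40, 50, 1)), c(1.5, 2), 5)
  half_diag <- sqrt(1.5^2 + 2^2) / 2
  set.seed(42)
  cc <- tangentfeat:::slice_coords(geom)
  for (i in 1:200) {
    mk <- rbind(c(runif(1, min(cc$x), max(cc$x)), runif(1, min(cc$y), max(cc$y))),
                c(runif(1, min(cc$x), max(cc$x)), runif(1, min(cc$y), max(cc$y))))
    det <- decode_heatmaps(make_heatmap_target(mk, geom), geom)
    expect_equal(nrow(det), 2)
    d1 <- sqrt((det$x[1] - mk[1, 1])^2 + (det$y[1] - mk[1, 2])^2)
    d2 <- sqrt((det$x[2] - mk[2, 1])^2 + (det$y[2] - mk[2, 2])^2)
    expect_lte(d1, half_diag + 1e-12)
    expect_lte(d2, half_diag + 1e-12)
  }
})

test_that("classical detector is exact on jitter-free phantoms", {
  for (wv in c(1L, 3L)) {
    p <- generate_phantom(tiny_spec(wire_voxels = wv, noise_sd = 10, seed = wv))
    det <- classical_detect(p$ct)
    rep <- detection_report(det, p$true_markers)
    expect_equal(rep$n_pairs, nrow(p$true_markers))
    expect_equal(rep$dist_mean, 0)
    expect_equal(rep$per_tolerance$tol_5$ap, 1)
    expect_equal(rep$per_tolerance$tol_5$ar, 1)
    # slices without wires yield no points
    expect_equal(sort(unique(det$slice)), sort(p$breast_slices))
  }
  # a volume without any breast-bearing slice gives an empty result
  p0 <- generate_phantom(tiny_spec(breast_radius = 0))
  expect_equal(nrow(classical_detect(p0$ct)), 0)
})
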