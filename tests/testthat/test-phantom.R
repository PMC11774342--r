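test_that("the default spherical grid rasterizes exactly 6 ring components", {
  spec <- phantom_spec("spherical_grid")
  truth <- rasterize_phantom(spec, voxel_size = 0.1,
                             extent = c(25, 25, 12))
  re <- truth$provenance$ring_enface
  lab <- EBImage::bwlabel(matrix(as.numeric(re), nrow(re), ncol(re)))
  expect_equal(max(lab), 6)
  # ring_count 0: dome surface only, no ring footprint
  bare <- rasterize_phantom(phantom_spec("spherical_grid", ring_count = 0),
                            voxel_size = 0.1, extent = c(25, 25, 12))
  expect_false(any(bare$provenance$ring_enface))
})

test_that("planar grid bar count follows floor(extent / pitch)", {
  spec <- phantom_spec("planar_grid", bar_pitch = 2, bar_width = 0.5,
                       grid_depth = 5)
  truth <- rasterize_phantom(spec, voxel_size = 0.1, extent = c(10, 10, 8))
  k <- which.min(abs(bscan3d:::volume_axis(truth, 3) - 5))
  sl <- truth$intensity[, , k] > 0.5
  # profile along x away from the y-bars: count bar components
  iy <- which.min(abs(bscan3d:::volume_axis(truth, 2) - 6))  # between bars
  runs <- rle(sl[, iy])
  expect_equal(sum(runs$values), 5)  # floor(10 / 2)
})

test_that("rasterization enforces the feature Nyquist guard", {
  expect_error(rasterize_phantom(phantom_spec("spherical_grid"),
                                 voxel_size = 0.2), "too coarse")
  expect_error(rasterize_phantom(phantom_spec("dome"), voxel_size = -1),
               "> 0")
})

test_that("frame simulation is deterministic and respects the truth extent", {
  truth <- small_dome_truth()
  probe <- ideal_probe()
  f1 <- simulate_bscan(truth, probe, 5, seed = 9, speckle_contrast = 0.5)
  f2 <- simulate_bscan(truth, probe, 5, seed = 9, speckle_contrast = 0.5)
  expect_identical(bscan3d:::unclass_frame(f1), bscan3d:::unclass_frame(f2))
  f3 <- simulate_bscan(truth, probe, 5, seed = 10, speckle_contrast = 0.5)
  expect_gt(mean(abs(f1 - f3)), 1)
  expect_error(simulate_bscan(truth, probe, 99, seed = 1), "outside")
  cfg <- sweep_sim_config(probe, sweep_spec(1, 1), 30,
                          speckle_contrast = 0.5, speckle_seed = 4,
                          y_start = 5)
  s1 <- simulate_sweep(truth, cfg)
  s2 <- simulate_sweep(truth, cfg)
  expect_identical(frame_mats(s1$sequence), frame_mats(s2$sequence))
  expect_error(sweep_sim_config(probe, sweep_spec(1, 1), 5),
               "container_rate")
})

test_that("container duplication mirrors the native refresh rate", {
  truth <- small_dome_truth()
  # 1 s at 30 fps container, 11 fps native -> 30 frames, 11 distinct
  sim <- simulate_sweep(truth, sweep_sim_config(
    ideal_probe(rate = 11), sweep_spec(1, 1), 30,
    speckle_contrast = 0.3, speckle_seed = 1, y_start = 5))
  expect_equal(length(sim$sequence$frames), 30)
  expect_equal(length(sim$bundle$clean_frames), 11)
  # 2 s at 8 fps native -> 16 distinct contents
  sim8 <- simulate_sweep(truth, sweep_sim_config(
    ideal_probe(rate = 8), sweep_spec(1, 2), 30,
    speckle_contrast = 0.3, speckle_seed = 1, y_start = 5))
  expect_equal(length(sim8$bundle$clean_frames), 16)
  # duplicates are exact copies
  ci <- sim$bundle$content_index
  dup <- which(ci == ci[1])
  expect_identical(bscan3d:::unclass_frame(sim$sequence$frames[[dup[1]]]),
                   bscan3d:::unclass_frame(sim$sequence$frames[[dup[2]]]))
})

test_that("clean sweeps equal the ground-truth frames exactly", {
  truth <- small_dome_truth()
  sim <- simulate_sweep(truth, sweep_sim_config(
    ideal_probe(), sweep_spec(1, 1), 11, speckle_contrast = 0,
    drift_per_frame = c(0, 0), overlay = "none", y_start = 5))
  for (j in c(1, 6, 11))
    expect_identical(bscan3d:::unclass_frame(sim$sequence$frames[[j]]),
                     bscan3d:::unclass_frame(sim$bundle$clean_frames[[j]]))
})

test_that("the rendered point-spread width matches the probe PSF", {
  tr <- array(0, c(81, 5, 81)); tr[41, , 41] <- 1
  tv <- us_volume(tr, rep(0.05, 3))
  pr <- probe_spec("p", 12, 11, 4, pixel_spacing = c(0.05, 0.05),
                   psf_axial_fwhm = 0.3, psf_lateral_fwhm = 0.6)
  fr <- simulate_bscan(tv, pr, 0.1)
  img <- bscan3d:::unclass_frame(fr)
  pk <- arrayInd(which.max(img), dim(img))
  ax <- fwhm_interp_oracle(img[, pk[2]], 0.05)
  lat <- fwhm_interp_oracle(img[pk[1], ], 0.05)
  expect_lt(abs(ax - 0.3) / 0.3, 0.1)
  expect_lt(abs(lat - 0.6) / 0.6, 0.1)
})

test_that("speckle is unit-mean over seeds where clipping is negligible", {
  tv <- us_volume(array(0.2, c(30, 5, 30)), rep(0.1, 3))
  pr <- ideal_probe()
  mns <- vapply(1:100, function(s)
    mean(bscan3d:::unclass_frame(
      simulate_bscan(tv, pr, 0.2, seed = s, speckle_contrast = 1))), 0)
  expect_lt(abs(mean(mns) / (0.2 * 255) - 1), 0.05)
})
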