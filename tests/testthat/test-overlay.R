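test_that("temporal statistics match hand and two-pass oracles", {
  const <- frame_sequence(lapply(0:3, function(i)
    bscan_frame(matrix(37, 8, 8), timestamp = i / 10)), 10)
  st <- temporal_statistics(const)
  expect_true(all(st$mean_image == 37))
  expect_true(all(st$sd_image == 0))
  # alternating 0/100 over an even count: mean 50, population SD 50
  alt <- frame_sequence(lapply(0:3, function(i)
    bscan_frame(matrix(ifelse(i %% 2 == 0, 0, 100), 8, 8),
                timestamp = i / 10)), 10)
  st <- temporal_statistics(alt)
  expect_true(all(st$mean_image == 50))
  expect_true(all(st$sd_image == 50))
  # seeded random sequence vs two-pass oracle
  set.seed(11)
  mats <- lapply(1:7, function(i) matrix(stats::runif(600) * 255, 20, 30))
  seqn <- frame_sequence(lapply(seq_along(mats), function(i)
    bscan_frame(mats[[i]], timestamp = i / 10)), 10)
  st <- temporal_statistics(seqn)
  oracle <- two_pass_stats_oracle(mats)
  expect_equal(st$mean_image, oracle$mean, tolerance = 1e-9)
  expect_equal(st$sd_image, oracle$sd, tolerance = 1e-9)
  expect_error(temporal_statistics(frame_sequence(list(
    bscan_frame(matrix(0, 4, 4))), 10)), "at least 2")
})

test_that("a static crosshair is detected against moving speckle", {
  truth <- small_dome_truth()
  sim <- simulate_sweep(truth, sweep_sim_config(
    ideal_probe(), sweep_spec(2, 6), 11, speckle_contrast = 0.4,
    speckle_seed = 2, overlay = "crosshair", y_start = 2))
  st <- temporal_statistics(sim$sequence)
  mobj <- detect_overlay_mask(st)
  gt <- sim$bundle$overlay_mask
  recall <- sum(mobj$mask & gt) / sum(gt)
  fpr <- sum(mobj$mask & !gt) / sum(!gt)
  expect_gte(recall, 0.99)
  expect_lte(fpr, 0.01)
})

test_that("bright but moving structure is not flagged as overlay", {
  # a bright bar translating 2 px per frame: high mean where it passes,
  # but high temporal SD everywhere it appears
  frames <- lapply(0:9, function(i) {
    m <- matrix(20, 60, 60)
    c0 <- 5 + 2 * i
    m[20:40, c0:(c0 + 3)] <- 255
    bscan_frame(m, timestamp = i / 10)
  })
  st <- temporal_statistics(frame_sequence(frames, 10))
  mobj <- detect_overlay_mask(st)
  expect_equal(sum(mobj$mask), 0L)
  # all-black sequence: empty mask, coverage 0
  dark <- frame_sequence(lapply(0:3, function(i)
    bscan_frame(matrix(0, 10, 10), timestamp = i / 10)), 10)
  expect_warning(m0 <- detect_overlay_mask(temporal_statistics(dark)),
                 "degenerate")
  expect_equal(m0$coverage, 0)
})

test_that("mask thresholds act monotonically", {
  truth <- small_dome_truth()
  sim <- simulate_sweep(truth, sweep_sim_config(
    ideal_probe(), sweep_spec(2, 4), 11, speckle_contrast = 0.4,
    speckle_seed = 6, overlay = "scale_bar", y_start = 3))
  st <- temporal_statistics(sim$sequence)
  # raising sd_ceiling never shrinks the mask
  m1 <- detect_overlay_mask(st, sd_ceiling = 0.5, min_area = 1)
  m2 <- detect_overlay_mask(st, sd_ceiling = 2.0, min_area = 1)
  expect_true(all(m2$mask[m1$mask]))
  # raising the intensity quantile never grows it
  q1 <- detect_overlay_mask(st, intensity_quantile = 0.95, min_area = 1)
  q2 <- detect_overlay_mask(st, intensity_quantile = 0.995, min_area = 1)
  expect_true(all(q1$mask[q2$mask]))
})

test_that("overlay removal touches only masked pixels and inpaints well", {
  # masked pixel surrounded by value 10 is filled with 10
  frames <- lapply(0:2, function(i)
    bscan_frame(matrix(10, 9, 9), timestamp = i / 10))
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  out <- remove_overlay(frame_sequence(frames, 10), m)
  expect_equal(bscan3d:::unclass_frame(out$frames[[1]])[5, 5], 10)
  # empty mask: identity
  out2 <- remove_overlay(frame_sequence(frames, 10), matrix(FALSE, 9, 9))
  expect_identical(frame_mats(out2), frame_mats(frame_sequence(frames, 10)))
  # coverage guard
  big <- matrix(TRUE, 9, 9); big[1:4, ] <- FALSE
  expect_error(remove_overlay(frame_sequence(frames, 10), big), "50%")
})

test_that("inpainting beats the overlaid frames by 10x RMSE on masked pixels", {
  truth <- small_dome_truth()
  sim <- simulate_sweep(truth, sweep_sim_config(
    ideal_probe(), sweep_spec(2, 6), 11, speckle_contrast = 0.4,
    speckle_seed = 2, overlay = "crosshair", y_start = 2))
  st <- temporal_statistics(sim$sequence)
  mobj <- detect_overlay_mask(st)
  cleaned <- remove_overlay(sim$sequence, mobj)
  m <- mobj$mask
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  j <- 30
  clean <- bscan3d:::unclass_frame(
    sim$bundle$clean_frames[[sim$bundle$content_index[j] + 1]])
  overlaid <- bscan3d:::unclass_frame(sim$sequence$frames[[j]])
  filled <- bscan3d:::unclass_frame(cleaned$frames[[j]])
  expect_gt(rmse(overlaid[m], clean[m]) / rmse(filled[m], clean[m]), 10)
  # unmasked pixels bit-identical
  expect_identical(overlaid[!m], filled[!m])
})
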