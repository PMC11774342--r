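test_that("noise statistics match hand computations and defaults", {
  u <- bscan_frame(matrix(50, 20, 20))
  r <- noise_stats(u)
  expect_equal(r$mean_signal, 50)
  expect_equal(r$noise_sd, 0)
  # half 0 half 100: mu 50, sigma 50
  m <- matrix(c(0, 100), 10, 10)
  r2 <- noise_stats(bscan_frame(m), roi = c(1, 1, 10, 10))
  expect_equal(r2$mean_signal, 50)
  expect_equal(r2$noise_sd, 50)
  # default roi equals the explicit central 50% crop
  set.seed(8)
  f <- bscan_frame(matrix(stats::runif(1600) * 255, 40, 40))
  expect_equal(noise_stats(f)$mean_signal,
               noise_stats(f, roi = c(11, 11, 20, 20))$mean_signal)
  expect_error(noise_stats(f, roi = c(35, 35, 20, 20)), "bounds")
})

test_that("noise statistics agree with a two-pass oracle to 1e-9", {
  set.seed(13)
  m <- matrix(stats::runif(900) * 255, 30, 30)
  r <- noise_stats(bscan_frame(m), roi = c(1, 1, 30, 30))
  mu <- mean(m)
  expect_equal(r$mean_signal, mu, tolerance = 1e-9)
  expect_equal(r$noise_sd, sqrt(mean((m - mu)^2)), tolerance = 1e-9)
})

test_that("feature centroids land on physical positions", {
  img <- matrix(0, 100, 100)
  img[48:52, 38:42] <- 200  # square blob
  fr <- bscan_frame(img, pixel_spacing = c(0.1, 0.1),
                    origin = c(x = 0, z = 0))
  cen <- feature_centroids(fr, 100)
  expect_equal(nrow(cen), 1)
  expect_equal(cen$x, (40 - 1) * 0.1, tolerance = 0.05)
  expect_equal(cen$z, (50 - 1) * 0.1, tolerance = 0.05)
  # two blobs sorted by lateral position
  img[18:22, 68:72] <- 200
  cen2 <- feature_centroids(bscan_frame(img, pixel_spacing = c(0.1, 0.1),
                                        origin = c(x = 0, z = 0)), 100)
  expect_equal(nrow(cen2), 2)
  expect_true(cen2$x[1] < cen2$x[2])
})

test_that("weighted centroids match the brute-force oracle", {
  set.seed(21)
  img <- matrix(0, 40, 40)
  blob_r <- 10:18; blob_c <- 20:26
  img[blob_r, blob_c] <- 100 + stats::runif(63) * 155
  fr <- bscan_frame(img, pixel_spacing = c(0.2, 0.25),
                    origin = c(x = -2, z = 1))
  cen <- feature_centroids(fr, 50)
  # oracle: direct weighted sums over all pixels above floor
  idx <- which(img >= 50)
  rows <- ((idx - 1) %% 40) + 1; cols <- ((idx - 1) %/% 40) + 1
  w <- img[idx]
  expect_equal(cen$x, sum(w * (-2 + (cols - 1) * 0.25)) / sum(w),
               tolerance = 1e-12)
  expect_equal(cen$z, sum(w * (1 + (rows - 1) * 0.2)) / sum(w),
               tolerance = 1e-12)
})

test_that("circle fit recovers curvature and degenerates gracefully", {
  # collinear -> curvature 0
  lin <- data.frame(x = 1:5, z = 2 * (1:5) + 1)
  expect_equal(curvature_and_angulation(lin)$curvature, 0)
  # points on a radius-20 circle -> curvature 0.05 within 1e-6
  th <- seq(-0.4, 0.4, length.out = 7)
  circ <- data.frame(x = 20 * sin(th), z = 30 - 20 * cos(th))
  expect_equal(curvature_and_angulation(circ)$curvature, 0.05,
               tolerance = 1e-6)
  # rigid motion invariance
  ang <- 0.7
  rot <- data.frame(x = cos(ang) * circ$x - sin(ang) * circ$z + 3,
                    z = sin(ang) * circ$x + cos(ang) * circ$z - 5)
  expect_equal(curvature_and_angulation(rot)$curvature, 0.05,
               tolerance = 1e-6)
  # chord length: first-to-last distance
  expect_equal(curvature_and_angulation(lin)$chord_length,
               sqrt(16 + 64))
  # < 3 centroids: curvature reported absent
  expect_true(is.na(curvature_and_angulation(lin[1:2, ])$curvature))
})

test_that("ring metrics count synthetic rings and ignore intensity scale", {
  # build a volume with 4 concentric rings in its en-face plane
  n <- 121; voxel <- 0.1
  xs <- (0:(n - 1)) * voxel - 6
  rho <- sqrt(outer(xs^2, xs^2, "+"))
  ef <- matrix(0.1, n, n)
  for (k in 1:4) ef[abs(rho - k * 1.2) < 0.15] <- 1
  vol <- us_volume(array(rep(ef, 3), c(n, n, 3)), rep(voxel, 3))
  rr <- ring_profile_metrics(vol)
  expect_equal(rr$ring_count, 4)
  expect_equal(rr$ring_positions, (1:4) * 1.2, tolerance = 0.1)
  expect_equal(rr$median_ring_width, 0.3, tolerance = 0.12)
  # invariance to rescaling (prominence is relative)
  vol2 <- us_volume(vol$intensity * 37 + 5, rep(voxel, 3))
  expect_equal(ring_profile_metrics(vol2)$ring_count, 4)
  # uniform volume: no rings
  uni <- us_volume(array(7, c(20, 20, 4)), rep(0.1, 3))
  expect_equal(ring_profile_metrics(uni)$ring_count, 0)
  expect_error(ring_profile_metrics(vol, prominence = 1.5), "prominence")
})

test_that("step roughness is tiny on smooth surfaces and linear in step height", {
  # densely sampled hemisphere with a graded (anti-aliased) boundary so
  # the subvoxel crossing detection can resolve the true surface
  n <- 81; voxel <- 0.1
  xs <- (0:(n - 1)) * voxel - 4
  zg <- (0:59) * voxel
  vol <- array(0, c(n, n, 60))
  for (iy in 1:n) {
    lat2 <- xs^2 + xs[iy]^2
    # shallow cap only: slopes bounded, surface analytically smooth
    zsurf <- ifelse(lat2 < 2.25, 1 + (3 - sqrt(pmax(9 - lat2, 0))), NA)
    for (ix in 1:n) if (!is.na(zsurf[ix]))
      vol[ix, iy, ] <- 255 * pmin(pmax((zg - zsurf[ix]) / (2 * voxel), 0), 1)
  }
  smooth <- us_volume(vol, rep(voxel, 3))
  expect_lt(step_artifact_metric(smooth, lateral_smooth = 5L), 0.01)
  # staircase: roughness proportional to step height
  stair <- function(h) {
    v <- array(0, c(8, 40, 30))
    z <- rep(h * (0:7), each = 5)[1:40]
    for (iy in 1:40) v[, iy, (round(z[iy] / 0.1) + 10):30] <- 1
    us_volume(v, rep(0.1, 3))
  }
  r1 <- step_artifact_metric(stair(0.1), lateral_smooth = 1L)
  r2 <- step_artifact_metric(stair(0.2), lateral_smooth = 1L)
  expect_equal(r2 / r1, 2, tolerance = 0.05)
  # no surface -> error
  expect_error(step_artifact_metric(us_volume(array(0, c(4, 4, 4)),
                                              rep(0.1, 3))), "surface")
})
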