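test_that("pixel_to_physical matches the closed-form polar conversion", {
  g <- sector_geometry(apex_offset = 0, angular_span = 60,
                       radial_min = 0, radial_max = 20)
  # on-axis ray at r = 10 mm: center column of an odd grid
  p <- pixel_to_physical(51, 51, g, c(101, 101))
  expect_equal(p$x, 0)
  expect_equal(p$z, 10)
  # theta = 30 deg, r = 20 mm: r sin/cos hand computation
  p <- pixel_to_physical(101, 101, g, c(101, 101))
  expect_equal(p$x, 10, tolerance = 1e-12)
  expect_equal(p$z, 17.3205080757, tolerance = 1e-9)
  # apex offset shifts depth only
  g2 <- sector_geometry(apex_offset = 3, angular_span = 60,
                        radial_min = 0, radial_max = 20)
  p2 <- pixel_to_physical(101, 51, g2, c(101, 101))
  expect_equal(p2$z, 17)
  expect_error(pixel_to_physical(0, 1, g, c(101, 101)), "out of range")
  expect_error(pixel_to_physical(1, 102, g, c(101, 101)), "out of range")
  expect_error(pixel_to_physical(1, 1, g, c(1, 101)), "degenerate")
})

test_that("narrow-fan limit approaches the linear-array mapping", {
  # with a tiny angular span, x ~ r_mid * theta: compare against the
  # equivalent linear column pitch at the middle row
  g <- sector_geometry(apex_offset = 0, angular_span = 0.5,
                       radial_min = 10, radial_max = 10.2)
  cols <- 41; rows <- 21
  mid <- (rows + 1) / 2
  r_mid <- 10.1
  pitch <- r_mid * (0.5 * pi / 180) / (cols - 1)
  for (col in c(1, 11, 21, 31, 41)) {
    p <- pixel_to_physical(mid, col, g, c(rows, cols))
    expect_equal(p$x, (col - (cols + 1) / 2) * pitch, tolerance = 1e-4)
  }
})

test_that("pixel_to_physical is injective over the fan", {
  g <- sector_geometry(apex_offset = 2, angular_span = 70,
                       radial_min = 1, radial_max = 9)
  grid <- expand.grid(row = 1:12, col = 1:15)
  p <- pixel_to_physical(grid$row, grid$col, g, c(12, 15))
  keys <- paste(round(p$x, 9), round(p$z, 9))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("scan conversion flattens a flat reflector rendered in polar", {
  geom <- sector_geometry(apex_offset = 2, angular_span = 70,
                          radial_min = 2, radial_max = 14,
                          rays_per_frame = 181, samples_per_ray = 241)
  # forward-render a flat reflector at depth z0: bright where the pixel's
  # physical depth is within half a band of z0
  z0 <- 8
  nrw <- 241; ncl <- 181
  pp <- pixel_to_physical(rep(1:nrw, ncl), rep(1:ncl, each = nrw),
                          geom, c(nrw, ncl))
  img <- matrix(ifelse(abs(pp$z - z0) < 0.25, 255, 0), nrw, ncl)
  fr <- bscan_frame(img, pixel_spacing = c(0.05, 0.05))
  # in the raw polar frame the ridge row varies strongly across columns
  ridge_row <- apply(img, 2, function(col) mean(which(col > 0)))
  expect_gt(diff(range(ridge_row)) * 0.05, 1)  # > 1 mm apparent bending
  out <- scan_convert(fr, geom, 0.05)
  m <- bscan3d:::unclass_frame(out)
  valid_cols <- which(colSums(m > 0) > 0)
  # away from the fan edge, detected ridge depth is flat within 1 px
  inner <- valid_cols[seq(20, length(valid_cols) - 20)]
  ridge <- vapply(inner, function(j) {
    w <- m[, j]; sum(seq_along(w) * w) / sum(w)
  }, 0)
  expect_lt(max(ridge) - min(ridge), 1)
})

test_that("identity scan conversion and zero frames behave trivially", {
  img <- speckle_matrix(1, 40, 50)
  fr <- bscan_frame(img, pixel_spacing = c(0.1, 0.1))
  out <- scan_convert(fr, NULL, c(0.1, 0.1))
  expect_identical(bscan3d:::unclass_frame(out), img)
  zero <- bscan_frame(matrix(0, 30, 30), pixel_spacing = c(0.1, 0.1))
  g <- sector_geometry(apex_offset = 1, angular_span = 60,
                       radial_min = 1, radial_max = 4)
  zc <- scan_convert(zero, g, 0.1)
  expect_true(all(bscan3d:::unclass_frame(zc) == 0))
  expect_error(scan_convert(fr, g, -0.1), "out_spacing")
})

test_that("identity-resampling round trip reproduces smooth images", {
  # resample up then back at the original spacing; smooth content should
  # survive within 2% of dynamic range
  x <- outer(seq(0, 1, length.out = 60), seq(0, 1, length.out = 80),
             function(a, b) 127 + 100 * sin(4 * a) * cos(5 * b))
  fr <- bscan_frame(x, pixel_spacing = c(0.1, 0.1))
  up <- scan_convert(fr, NULL, c(0.05, 0.05))
  back <- scan_convert(up, NULL, c(0.1, 0.1))
  m <- bscan3d:::unclass_frame(back)
  rmse <- sqrt(mean((m - x)^2))
  expect_lt(rmse, 0.02 * diff(range(x)))
})

test_that("slice positions follow constant-speed kinematics", {
  sw <- sweep_spec(speed = 1, duration = 2)
  expect_equal(slice_position(0, sw, 11), 0)
  expect_equal(slice_position(11, sw, 11), 1)
  expect_equal(slice_position(1, sweep_spec(9, 2), 11), 9 / 11)
  # strictly increasing, equally spaced at speed/rate
  y <- slice_position(0:21, sweep_spec(2, 2), 11)
  expect_true(all(diff(y) > 0))
  expect_equal(unique(round(diff(y), 12)), 2 / 11, tolerance = 1e-9)
  expect_error(slice_position(-1, sw, 11), ">= 0")
  expect_error(slice_position(1, sw, 0), "> 0")
})

test_that("probe presets load from the shipped key-value configs", {
  a12 <- probe_preset("A12")
  expect_s3_class(a12, "probe_spec")
  expect_equal(a12$native_frame_rate, 11)
  expect_null(a12$sector)
  aq20 <- probe_preset("AQ20")
  expect_equal(aq20$native_frame_rate, 8)
  biq <- probe_preset("BiQ")
  expect_s3_class(biq$sector, "sector_geometry")
  expect_error(probe_preset("nope"), "unknown probe preset")
})
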