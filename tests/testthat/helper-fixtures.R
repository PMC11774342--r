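# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no stored data.

# textured test frame: blurred uniform noise, speckle-like
speckle_matrix <- function(seed, nr = 100, nc = 100, blur = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(nr * nc) * 255, nr, nc)
  if (blur > 0) m <- bscan3d:::blur_separable(m, blur, blur)
  m
}

# uniform echogenicity truth volume for registration/noise experiments
uniform_truth <- function(level = 0.5, dims = c(121, 81, 81), voxel = 0.1) {
  us_volume(array(level, dims), rep(voxel, 3))
}

small_dome_truth <- function(radius = 10, voxel = 0.1) {
  rasterize_phantom(phantom_spec("dome", dome_radius = radius),
                    voxel_size = voxel, extent = c(16, 16, 8),
                    apex_depth = 2)
}

ideal_probe <- function(pixel = 0.1, rate = 11, psf_ax = 0.2, psf_lat = 0.3) {
  probe_spec("ideal", center_frequency = 12, native_frame_rate = rate,
             imaging_depth = 8, pixel_spacing = c(pixel, pixel),
             psf_axial_fwhm = psf_ax, psf_lateral_fwhm = psf_lat)
}

# exhaustive integer-shift sum-of-squared-differences search: independent
# oracle for register_pair (same output convention: correction applied to
# `moving`)
ssd_search_oracle <- function(reference, moving, m) {
  nr <- nrow(moving); nc <- ncol(moving)
  rb <- (1 + m):(nr - m); cb <- (1 + m):(nc - m)
  best <- Inf; best_dy <- 0; best_dx <- 0
  for (dy in -m:m) for (dx in -m:m) {
    ssd <- sum((moving[rb, cb] - reference[rb + dy, cb + dx])^2)
    if (ssd < best) { best <- ssd; best_dy <- dy; best_dx <- dx }
  }
  c(dx = best_dx, dy = best_dy)
}

# two-pass mean / population-SD oracle for temporal statistics
two_pass_stats_oracle <- function(frames) {
  n <- length(frames)
  mu <- Reduce(`+`, frames) / n
  v <- Reduce(`+`, lapply(frames, function(f) (f - mu)^2)) / n
  list(mean = mu, sd = sqrt(v))
}

# FWHM by linear interpolation of the half-maximum crossings
fwhm_interp_oracle <- function(p, spacing) {
  h <- max(p) / 2
  i <- which.max(p)
  j <- i; while (j > 1 && p[j - 1] >= h) j <- j - 1
  left <- if (j == 1) 1 else (j - 1) + (h - p[j - 1]) / (p[j] - p[j - 1])
  j <- i; while (j < length(p) && p[j + 1] >= h) j <- j + 1
  right <- if (j == length(p)) length(p)
           else (j + 1) - (h - p[j + 1]) / (p[j] - p[j + 1])
  (right - left) * spacing
}

# least-squares sphere through surface points of a reconstruction:
# oracle for dome-radius recovery
fit_dome_radius <- function(vol, stride = 3L) {
  v <- vol$intensity; d <- dim(v)
  thr <- max(v) / 2
  xs <- bscan3d:::volume_axis(vol, 1)
  ys <- bscan3d:::volume_axis(vol, 2)
  zs <- bscan3d:::volume_axis(vol, 3)
  pts <- list()
  for (iy in seq(1, d[2], by = stride)) {
    sl <- v[, iy, ]
    for (ix in seq(1, d[1], by = stride)) {
      k <- which(sl[ix, ] >= thr)[1]
      if (!is.na(k) && k > 1) pts[[length(pts) + 1]] <- c(xs[ix], ys[iy], zs[k])
    }
  }
  pts <- do.call(rbind, pts)
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 2 * pts[, 3], 1)
  s <- qr.solve(A, rowSums(pts^2))
  sqrt(s[4] + sum(s[1:3]^2))
}

# frame list -> plain matrices
frame_mats <- function(seqn) lapply(seqn$frames, bscan3d:::unclass_frame)
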