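# Quantitative quality metrics for frames and reconstructed volumes:
# noise statistics of homogeneous regions, curvature/angulation artifacts
# of grid phantoms, resolvability of concentric rings, and the stepwise
# surface artifact that appears when the sweep outruns the frame rate.

#' Mean signal and noise of a region of interest
#'
#' @param frame A [bscan_frame()] (or matrix).
#' @param roi `c(row0, col0, rows, cols)` (1-based corner); default the
#'   central 50% crop of the frame, the usual "non-border" sampling
#'   region.
#' @return An object of class `noise_report`: list with `mean_signal`
#'   (mu), `noise_sd` (sigma, population SD), `roi`, `n_pixels`.
#' @export
noise_stats <- function(frame, roi = NULL) {
  img <- if (inherits(frame, "bscan_frame")) unclass_frame(frame)
         else as.matrix(frame)
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(roi)) {
    r0 <- floor(nr / 4) + 1L; c0 <- floor(nc / 4) + 1L
    roi <- c(r0, c0, nr - 2L * (r0 - 1L), nc - 2L * (c0 - 1L))
  }
  roi <- as.integer(roi)
  r1 <- roi[1]; c1 <- roi[2]; r2 <- r1 + roi[3] - 1L; c2 <- c1 + roi[4] - 1L
  if (r1 < 1 || c1 < 1 || r2 > nr || c2 > nc)
    stop_invalid("roi outside frame bounds")
  v <- img[r1:r2, c1:c2]
  if (length(v) < 2) stop_invalid("roi must contain at least 2 pixels")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  structure(list(mean_signal = mu, noise_sd = sigma, roi = roi,
                 n_pixels = length(v)),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> mu = %.3f, sigma = %.3f over %d px\n",
              x$mean_signal, x$noise_sd, x$n_pixels))
  invisible(x)
}

#' Physical centroids and orientations of bright features
#'
#' Thresholds the frame, labels connected components, and returns the
#' intensity-weighted centroid and principal-axis orientation of each
#' component at least `min_area` pixels, in physical mm via the frame's
#' pixel spacing and origin. Components are sorted by lateral position.
#'
#' @param frame A [bscan_frame()].
#' @param intensity_floor Threshold in intensity levels.
#' @param min_area Minimum component area in pixels.
#' @return data.frame with columns `x`, `z` (mm), `area` (px) and
#'   `angle` (degrees of the principal axis relative to the image
#'   horizontal); zero rows when nothing exceeds the floor.
#' @export
feature_centroids <- function(frame, intensity_floor, min_area = 4L) {
  img <- unclass_frame(frame)
  sp <- frame_spacing(frame)
  org <- frame_origin(frame)
  lab <- label_components(img >= intensity_floor)
  nlab <- max(lab)
  if (nlab == 0)
    return(data.frame(x = numeric(0), z = numeric(0),
                      area = integer(0), angle = numeric(0)))
  out <- data.frame(x = numeric(0), z = numeric(0), area = integer(0),
                    angle = numeric(0))
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    if (length(idx) < min_area) next
    rows <- ((idx - 1L) %% nrow(img)) + 1L
    cols <- ((idx - 1L) %/% nrow(img)) + 1L
    wts <- img[idx]
    xs <- org["x"] + (cols - 1) * sp[2]
    zs <- org["z"] + (rows - 1) * sp[1]
    cx <- sum(wts * xs) / sum(wts)
    cz <- sum(wts * zs) / sum(wts)
    mu20 <- sum(wts * (xs - cx)^2) / sum(wts)
    mu02 <- sum(wts * (zs - cz)^2) / sum(wts)
    mu11 <- sum(wts * (xs - cx) * (zs - cz)) / sum(wts)
    angle <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    out <- rbind(out, data.frame(x = cx, z = cz, area = length(idx),
                                 angle = angle))
  }
  out[order(out$x), , drop = FALSE]
}

# Algebraic (Kasa) least-squares circle through 2D points:
# x^2 + y^2 = 2 a x + 2 b y + c. Returns center, radius.
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(cx = sol[1], cy = sol[2], radius = sqrt(r2))
}

#' Curvature and angulation artifact report for a grid phantom
#'
#' Fits a least-squares circle through the feature centroids; the
#' curvature (1/R, in 1/mm) quantifies the arc a physically flat grid is
#' bent into by raw sector-scan display, and drops to (numerically) zero
#' once the centroids are collinear. The chord length is the first-to-last
#' centroid distance, and per-feature angulation is the principal-axis
#' tilt of each component.
#'
#' @param centroids data.frame with `x`, `z` columns (mm), as returned by
#'   [feature_centroids()]; an `angle` column, when present, is carried
#'   through as the angulations.
#' @param feature_axes Optional numeric vector of per-feature segment
#'   angles (degrees), overriding the `angle` column.
#' @return An object of class `grid_artifact_report`: list with
#'   `centroids`, `chord_length` (mm), `curvature` (1/mm, `NA` for fewer
#'   than 3 centroids), `angulations` (degrees).
#' @export
curvature_and_angulation <- function(centroids, feature_axes = NULL) {
  n <- nrow(centroids)
  if (n < 1) stop_invalid("need at least one centroid")
  ang <- if (!is.null(feature_axes)) feature_axes
         else if ("angle" %in% names(centroids)) centroids$angle
         else rep(NA_real_, n)
  chord <- if (n >= 2)
    sqrt((centroids$x[n] - centroids$x[1])^2 +
         (centroids$z[n] - centroids$z[1])^2) else 0
  curvature <- NA_real_
  if (n >= 3) {
    x <- centroids$x; z <- centroids$z
    # collinearity check: perpendicular spread around the best-fit line
    xm <- x - mean(x); zm <- z - mean(z)
    sv <- svd(cbind(xm, zm))
    scale <- max(sv$d[1], 1e-12)
    if (sv$d[2] / scale < 1e-9) {
      curvature <- 0
    } else {
      fit <- fit_circle(x, z)
      curvature <- if (is.null(fit)) 0 else 1 / fit$radius
    }
  }
  structure(list(centroids = centroids, chord_length = chord,
                 curvature = curvature, angulations = ang),
            class = "grid_artifact_report")
}

#' @export
print.grid_artifact_report <- function(x, ...) {
  cat(sprintf(
    "<grid_artifact_report> %d features, chord %.3f mm, curvature %s /mm\n",
    nrow(x$centroids), x$chord_length,
    if (is.na(x$curvature)) "NA" else sprintf("%.5f", x$curvature)))
  invisible(x)
}

# Local maxima with topographic prominence of a 1D profile. Plateaus
# (runs of equal values flanked by lower neighbors) count as one peak at
# their center. Returns data.frame(index, height, prominence).
peaks_with_prominence <- function(p) {
  n <- length(p)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  runs <- rle(p)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  nr <- length(runs$values)
  if (nr < 3) return(empty)
  is_max <- which(vapply(seq_len(nr), function(k)
    k > 1 && k < nr && runs$values[k] > runs$values[k - 1] &&
      runs$values[k] > runs$values[k + 1], TRUE))
  if (length(is_max) == 0) return(empty)
  is_peak <- as.integer(round((starts[is_max] + ends[is_max]) / 2))
  prom <- vapply(is_peak, function(i) {
    h <- p[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1 && p[j] <= h) { lmin <- min(lmin, p[j]); j <- j - 1L }
    left_base <- if (j >= 1) lmin else min(p[1:i])
    rmin <- h
    j <- i + 1L
    while (j <= n && p[j] <= h) { rmin <- min(rmin, p[j]); j <- j + 1L }
    right_base <- if (j <= n) rmin else min(p[i:n])
    h - max(left_base, right_base)
  }, 0)
  data.frame(index = is_peak, height = p[is_peak], prominence = prom)
}

# Full width of peak `i` at level height - prominence/2, by linear
# interpolation of the nearest crossings; dist = x-coordinates of p.
peak_half_prominence_width <- function(p, dist, i, prominence) {
  level <- p[i] - prominence / 2
  n <- length(p)
  j <- i
  while (j > 1 && p[j - 1] > level) j <- j - 1L
  left <- if (j == 1) dist[1] else {
    f <- (level - p[j - 1]) / (p[j] - p[j - 1])
    dist[j - 1] + f * (dist[j] - dist[j - 1])
  }
  j <- i
  while (j < n && p[j + 1] > level) j <- j + 1L
  right <- if (j == n) dist[n] else {
    f <- (level - p[j + 1]) / (p[j] - p[j + 1])
    dist[j + 1] - f * (dist[j + 1] - dist[j])
  }
  right - left
}

#' Ring resolvability metrics of a dome reconstruction
#'
#' Projects the volume en face (maximum intensity along depth), averages
#' intensity over annuli around the dome center, and detects ring peaks
#' in the resulting radial profile by relative topographic prominence.
#' Ring count and the median full width at half prominence quantify what
#' a reader would call "how many rings are resolved, and how sharp".
#'
#' @param volume An [us_volume()].
#' @param dome_center `(x, y)` mm of the dome apex in volume coordinates;
#'   default the intensity-weighted centroid of the en-face projection
#'   (exact for a centered, rotationally symmetric phantom).
#' @param prominence Fraction in (0, 1) of the profile's dynamic range a
#'   peak must rise above its surroundings to count as a ring
#'   (default 0.2).
#' @param dome_radius Optional dome radius in mm. When given, en-face
#'   radial distances are converted to arc distances along the dome
#'   surface (`s = R asin(rho / R)`), so ring widths are measured along
#'   the surface where the physical ring width is defined; otherwise
#'   distances are in the projection plane.
#' @return An object of class `ring_report`: list with `radial_profile`
#'   (data.frame distance/intensity), `ring_count`, `ring_positions`
#'   (mm), `median_ring_width` (mm, `NA` when no rings detected).
#' @export
ring_profile_metrics <- function(volume, dome_center = NULL,
                                 prominence = 0.2, dome_radius = NULL) {
  if (prominence <= 0 || prominence >= 1)
    stop_invalid("prominence must be in (0, 1)")
  ef <- enface_projection(volume)
  if (all(ef == ef[1]) || sum(ef) == 0) {
    if (sum(ef) == 0) stop_invalid("en-face projection is empty")
  }
  xs <- volume_axis(volume, 1)
  ys <- volume_axis(volume, 2)
  if (is.null(dome_center)) {
    w <- ef - min(ef)
    tot <- sum(w)
    dome_center <- if (tot > 0)
      c(sum(outer(xs, rep(1, length(ys))) * w) / tot,
        sum(outer(rep(1, length(xs)), ys) * w) / tot)
      else c(mean(xs), mean(ys))
  }
  rho <- sqrt(outer((xs - dome_center[1])^2, (ys - dome_center[2])^2, "+"))
  dist <- rho
  if (!is.null(dome_radius))
    dist <- dome_radius * asin(pmin(rho / dome_radius, 1))
  dr <- min(volume$voxel_spacing[1:2])
  bins <- floor(dist / dr) + 1L
  prof <- tapply(as.vector(ef), as.vector(bins), mean)
  centers <- (as.integer(names(prof)) - 0.5) * dr
  p <- as.numeric(prof)
  rng <- diff(range(p))
  if (rng == 0) {
    return(structure(list(
      radial_profile = data.frame(distance = centers, intensity = p),
      ring_count = 0L, ring_positions = numeric(0),
      median_ring_width = NA_real_), class = "ring_report"))
  }
  pk <- peaks_with_prominence(p)
  pk <- pk[pk$prominence >= prominence * rng, , drop = FALSE]
  widths <- vapply(seq_len(nrow(pk)), function(i)
    peak_half_prominence_width(p, centers, pk$index[i], pk$prominence[i]), 0)
  structure(list(
    radial_profile = data.frame(distance = centers, intensity = p),
    ring_count = nrow(pk),
    ring_positions = centers[pk$index],
    median_ring_width = if (nrow(pk)) stats::median(widths) else NA_real_),
    class = "ring_report")
}

#' @export
print.ring_report <- function(x, ...) {
  cat(sprintf("<ring_report> %d rings detected, median width %s mm\n",
              x$ring_count,
              if (is.na(x$median_ring_width)) "NA"
              else sprintf("%.3f", x$median_ring_width)))
  invisible(x)
}

#' Stepwise (staircase) surface artifact of a reconstruction
#'
#' Extracts the depth of the first threshold crossing per (x, y) column —
#' the phantom's top surface — and returns the root-mean-square of the
#' second difference of that depth map along the elevation axis. A surface
#' swept slowly enough is smooth (tiny second differences); sweeping
#' faster at a fixed frame rate spaces the slices out and linear
#' interpolation leaves chord-like steps whose size this metric tracks.
#'
#' @param volume An [us_volume()].
#' @param threshold Surface detection level; default half the volume
#'   maximum.
#' @param min_columns Minimum fraction of (x, y) columns that must
#'   contain a surface (default 0.05).
#' @param lateral_smooth Odd window length (voxels) of a running mean
#'   applied to the depth map along x before differencing (default 5).
#'   Step artifacts are elevation-axis structures, constant across the
#'   frame, so lateral smoothing suppresses per-column speckle jitter of
#'   the surface detection without touching the staircase itself; set to
#'   1 to disable.
#' @return Roughness in mm.
#' @export
step_artifact_metric <- function(volume, threshold = NULL,
                                 min_columns = 0.05, lateral_smooth = 5L) {
  v <- volume$intensity
  d <- dim(v)
  if (max(v) <= min(v))
    stop_invalid("no detectable surface: volume has no contrast")
  if (is.null(threshold)) threshold <- max(v) / 2
  if (threshold <= min(v))
    stop_invalid("no detectable surface: threshold below volume minimum")
  zsp <- volume$voxel_spacing[3]
  zmap <- matrix(NA_real_, d[1], d[2])
  above <- v >= threshold
  hit <- matrix(FALSE, d[1], d[2])
  for (k in seq_len(d[3])) {
    new <- above[, , k] & !hit
    if (any(new)) {
      if (k == 1) zmap[new] <- 0
      else {
        # subvoxel crossing between slices k-1 and k
        v0 <- v[, , k - 1][new]; v1 <- v[, , k][new]
        f <- (threshold - v0) / pmax(v1 - v0, 1e-12)
        f <- pmin(pmax(f, 0), 1)
        zmap[new] <- (k - 2 + f) * zsp
      }
      hit[new] <- TRUE
    }
  }
  if (mean(hit) < min_columns)
    stop_invalid("no detectable surface: fewer than ",
                 round(100 * min_columns), "% of columns cross threshold")
  lateral_smooth <- as.integer(lateral_smooth)
  if (lateral_smooth > 1) {
    # NA-aware running mean along x for each elevation column
    h <- lateral_smooth %/% 2L
    vals <- zmap; vals[is.na(vals)] <- 0
    cnt <- matrix(as.numeric(is.finite(zmap)), d[1], d[2])
    csum_v <- apply(rbind(0, vals), 2, cumsum)
    csum_c <- apply(rbind(0, cnt), 2, cumsum)
    lo <- pmax(seq_len(d[1]) - h, 1L); hi <- pmin(seq_len(d[1]) + h, d[1])
    sm_v <- csum_v[hi + 1L, , drop = FALSE] - csum_v[lo, , drop = FALSE]
    sm_c <- csum_c[hi + 1L, , drop = FALSE] - csum_c[lo, , drop = FALSE]
    sm <- sm_v / sm_c
    sm[sm_c == 0 | !is.finite(sm)] <- NA_real_
    sm[is.na(zmap)] <- NA_real_  # smoothing never invents a surface
    zmap <- sm
  }
  ny <- d[2]
  if (ny < 3) stop_invalid("need at least 3 elevation samples")
  d2 <- zmap[, 1:(ny - 2)] - 2 * zmap[, 2:(ny - 1)] + zmap[, 3:ny]
  d2 <- d2[is.finite(d2)]
  if (length(d2) == 0) stop_invalid("surface too sparse for roughness")
  sqrt(mean(d2^2))
}
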