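# Parametric test phantoms and the forward sweep simulator. Three phantom
# families mirror common 3D-ultrasound test objects: a planar bar grid, a
# dome ("wax dome"), and a dome carrying concentric rings plus radial
# spokes on its surface ("resin-style" spherical grid; by default 6 rings
# of 0.3 mm width). The echo model is deliberately simple — interface
# brightness, separable Gaussian point spread, multiplicative Rayleigh
# speckle — which is enough to exercise every pipeline stage; it is not a
# wave-propagation simulation and models neither shadowing nor
# attenuation.

#' Phantom specification
#'
#' @param variant `"planar_grid"`, `"spherical_grid"` or `"dome"`.
#' @param bar_pitch,bar_width,grid_depth Planar grid: bar spacing, bar
#'   width, and depth of the grid plane (mm).
#' @param dome_radius Dome/spherical-grid sphere radius (mm).
#' @param ring_count Number of concentric rings on the spherical grid.
#' @param ring_width Ring width (mm), measured along the dome surface.
#' @param ring_pitch Arc distance between consecutive rings (mm).
#' @param spoke_count Number of radial spokes crossing the rings.
#' @param surface_thickness Echogenic shell thickness of the dome (mm).
#' @param background_echogenicity,feature_echogenicity Relative scatter
#'   amplitudes (0..1) of the embedding medium and of grid/ring features.
#' @param surface_echogenicity Amplitude of the bare dome shell between
#'   features (spherical grid only; the bare dome uses
#'   `feature_echogenicity` for its surface).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(variant = c("spherical_grid", "planar_grid", "dome"),
                         bar_pitch = 2, bar_width = 0.5, grid_depth = 8,
                         dome_radius = 12, ring_count = 6L, ring_width = 0.3,
                         ring_pitch = 1.5, spoke_count = 8L,
                         surface_thickness = 0.3,
                         background_echogenicity = 0.1,
                         feature_echogenicity = 1.0,
                         surface_echogenicity = 0.4) {
  variant <- match.arg(variant)
  lens <- c(bar_pitch, bar_width, grid_depth, dome_radius, ring_width,
            ring_pitch, surface_thickness)
  if (any(lens <= 0)) stop_invalid("all phantom lengths must be > 0")
  if (ring_count < 0) stop_invalid("ring_count must be >= 0")
  if (feature_echogenicity <= background_echogenicity)
    stop_invalid("feature_echogenicity must exceed background_echogenicity")
  structure(list(variant = variant, bar_pitch = bar_pitch,
                 bar_width = bar_width, grid_depth = grid_depth,
                 dome_radius = dome_radius, ring_count = as.integer(ring_count),
                 ring_width = ring_width, ring_pitch = ring_pitch,
                 spoke_count = as.integer(spoke_count),
                 surface_thickness = surface_thickness,
                 background_echogenicity = background_echogenicity,
                 feature_echogenicity = feature_echogenicity,
                 surface_echogenicity = surface_echogenicity),
            class = "phantom_spec")
}

#' Rasterize a phantom into a ground-truth volume
#'
#' Produces a relative-amplitude (0..1) volume: background echogenicity
#' everywhere; feature echogenicity on the grid bars (planar grid) or on
#' the concentric rings and spokes of the dome surface (spherical grid);
#' the bare dome shell carries `surface_echogenicity` (spherical grid) or
#' `feature_echogenicity` (dome variant). Ring k occupies surface-arc
#' distances within `ring_width/2` of `k * ring_pitch` from the dome apex.
#'
#' For the spherical grid the provenance additionally carries
#' `ring_enface`, the en-face (x, y) footprint of the ring voxels alone,
#' so ring features can be counted independently of the spokes.
#'
#' @param spec A [phantom_spec()].
#' @param voxel_size Isotropic voxel edge in mm; must be at most
#'   `ring_width / 2` when rings are present (Nyquist for the features).
#' @param extent Domain size (x, y, z) in mm.
#' @param apex_depth Depth (mm) of the dome apex / top of the phantom.
#' @return An [us_volume()] with origin (0, 0, 0).
#' @export
rasterize_phantom <- function(spec, voxel_size = 0.1, extent = c(25, 25, 15),
                              apex_depth = 5) {
  if (voxel_size <= 0) stop_invalid("voxel_size must be > 0")
  if (spec$variant == "spherical_grid" && spec$ring_count > 0 &&
      voxel_size > spec$ring_width / 2)
    stop_invalid("voxel_size too coarse for ", spec$ring_width,
                 " mm rings: need <= ring_width/2")
  xs <- seq(0, extent[1], by = voxel_size)
  ys <- seq(0, extent[2], by = voxel_size)
  zs <- seq(0, extent[3], by = voxel_size)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  vol <- array(spec$background_echogenicity, c(nx, ny, nz))
  cx <- extent[1] / 2; cy <- extent[2] / 2

  if (spec$variant == "planar_grid") {
    half_h <- spec$surface_thickness / 2
    in_bar <- function(v) (v %% spec$bar_pitch) < spec$bar_width
    bar_xy <- outer(in_bar(xs - cx), rep(TRUE, ny)) |
              outer(rep(TRUE, nx), in_bar(ys - cy))
    for (k in which(abs(zs - spec$grid_depth) <= half_h))
      vol[, , k][bar_xy] <- spec$feature_echogenicity
    return(us_volume(vol, rep(voxel_size, 3),
                     provenance = list(phantom = spec$variant)))
  }

  # dome / spherical grid: sphere of radius Rd centered below the apex
  Rd <- spec$dome_radius
  zc <- apex_depth + Rd
  half_t <- spec$surface_thickness / 2
  shell_amp <- if (spec$variant == "dome") spec$feature_echogenicity
               else spec$surface_echogenicity
  lat2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  phi_az <- atan2(outer(rep(1, nx), ys - cy),
                  outer(xs - cx, rep(1, ny)))
  ring_enface <- matrix(FALSE, nx, ny)
  max_arc <- if (spec$ring_count > 0)
    spec$ring_count * spec$ring_pitch + spec$ring_width else 0
  for (k in seq_len(nz)) {
    dz2 <- (zs[k] - zc)^2
    d <- sqrt(lat2 + dz2)
    # anti-aliased shell: one-voxel soft edge avoids voxelization jaggies
    w <- pmin(pmax((half_t - abs(d - Rd)) / voxel_size + 0.5, 0), 1)
    if (zs[k] > zc) w[] <- 0  # upper hemisphere only
    shell <- w > 0.5
    if (!any(w > 0)) next
    sl <- matrix(spec$background_echogenicity, nx, ny)
    sl <- sl + w * (shell_amp - spec$background_echogenicity)
    if (spec$variant == "spherical_grid") {
      # arc distance from apex along the surface
      cosang <- pmin(1, pmax(-1, (zc - zs[k]) / pmax(d, 1e-9)))
      s <- Rd * acos(cosang)
      if (spec$ring_count > 0) {
        kring <- round(s / spec$ring_pitch)
        ring <- shell & kring >= 1 & kring <= spec$ring_count &
          abs(s - kring * spec$ring_pitch) <= spec$ring_width / 2
        sl[ring] <- spec$feature_echogenicity
        ring_enface <- ring_enface | ring
      }
      if (spec$spoke_count > 0) {
        spoke_step <- 2 * pi / spec$spoke_count
        az <- (phi_az %% spoke_step)
        az <- pmin(az, spoke_step - az)
        lat <- sqrt(lat2)
        spoke <- shell & s <= max(max_arc, 1e-9) &
          az * pmax(lat, voxel_size) <= spec$ring_width / 2
        sl[spoke] <- spec$feature_echogenicity
      }
    }
    vol[, , k] <- sl
  }
  prov <- list(phantom = spec$variant)
  if (spec$variant == "spherical_grid") prov$ring_enface <- ring_enface
  us_volume(vol, rep(voxel_size, 3), provenance = prov)
}

#' Sweep simulation configuration
#'
#' @param probe A [probe_spec()].
#' @param sweep A [sweep_spec()].
#' @param container_rate Screen-capture recording rate, frames/s; must be
#'   at least the probe's native rate.
#' @param speckle_seed Integer seed; the whole simulation is deterministic
#'   given it.
#' @param speckle_contrast Fraction in [0, 1]: 0 disables speckle, 1 is
#'   fully developed Rayleigh speckle.
#' @param drift_per_frame Length-2 `(dx, dy)` pixels of in-plane probe
#'   drift accumulated per native frame.
#' @param overlay `"none"`, `"crosshair"` or `"scale_bar"`.
#' @param y_start Elevation (mm) of the first slice within the phantom
#'   volume (default 0).
#' @param speckle_decorrelation Elevation distance (mm) over which the
#'   speckle pattern decorrelates between slices; defaults to the probe's
#'   lateral PSF width, the usual proxy for elevation beam thickness.
#'   Slices closer than this share most of their speckle, as overlapping
#'   beams do in a real sweep.
#' @return An object of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(probe, sweep, container_rate = 30,
                             speckle_seed = 1L, speckle_contrast = 0.3,
                             drift_per_frame = c(0, 0),
                             overlay = c("none", "crosshair", "scale_bar"),
                             y_start = 0, speckle_decorrelation = NULL) {
  overlay <- match.arg(overlay)
  if (container_rate < probe$native_frame_rate)
    stop_invalid("container_rate must be >= the probe's native frame rate")
  if (speckle_contrast < 0 || speckle_contrast > 1)
    stop_invalid("speckle_contrast must be in [0, 1]")
  if (is.null(speckle_decorrelation))
    speckle_decorrelation <- probe$psf_lateral_fwhm
  if (speckle_decorrelation <= 0)
    stop_invalid("speckle_decorrelation must be > 0")
  structure(list(probe = probe, sweep = sweep,
                 container_rate = container_rate,
                 speckle_seed = as.integer(speckle_seed),
                 speckle_contrast = speckle_contrast,
                 drift_per_frame = as.numeric(drift_per_frame),
                 overlay = overlay, y_start = y_start,
                 speckle_decorrelation = speckle_decorrelation),
            class = "sweep_sim_config")
}

# Rayleigh multiplier field with unit mean: sigma*sqrt(-2 log U),
# sigma = sqrt(2/pi).
rayleigh_unit <- function(n) sqrt(2 / pi) * sqrt(-2 * log(stats::runif(n)))

# Composite a synthetic overlay onto a frame matrix; returns the mask too.
compose_overlay <- function(img, type) {
  nr <- nrow(img); nc <- ncol(img)
  mask <- matrix(FALSE, nr, nc)
  if (type == "crosshair") {
    rmid <- round(nr / 2); cmid <- round(nc / 2)
    mask[rmid + 0:1, ] <- TRUE
    mask[, cmid + 0:1] <- TRUE
  } else if (type == "scale_bar") {
    col <- nc - 4L
    mask[, col + 0:1] <- TRUE
    ticks <- seq(1, nr, by = max(2L, nr %/% 10))
    for (tk in ticks) mask[tk:min(nr, tk + 1L), (col - 3L):(col + 1L)] <- TRUE
  }
  img[mask] <- 255
  list(image = img, mask = mask)
}

#' Simulate one B-scan frame from a ground-truth volume
#'
#' Extracts the (x, z) plane at elevation `y` (linear interpolation
#' between the truth's elevation slices), samples it on the probe's
#' native pixel grid — along sector rays when the probe has a
#' [sector_geometry()], on a regular Cartesian grid otherwise — convolves
#' with the probe's separable Gaussian point-spread function, multiplies
#' by seeded Rayleigh speckle of the configured contrast, and scales to
#' 8-bit levels. Deterministic given identical inputs and seed.
#'
#' @param truth An [us_volume()] of relative amplitudes (0..1).
#' @param probe A [probe_spec()].
#' @param y Elevation in mm; must lie within the truth extent.
#' @param seed Integer seed for the speckle field.
#' @param speckle_contrast Fraction in [0, 1].
#' @param overlay Overlay type composited onto the frame (default none).
#' @param speckle_field Optional pre-drawn unit-mean multiplier matrix of
#'   the frame's dimensions, used instead of drawing from `seed`
#'   ([simulate_sweep()] passes elevation-correlated fields here).
#' @return A [bscan_frame()]; polar frames carry their geometry in
#'   attribute `sector`, and any overlay mask in attribute
#'   `overlay_mask`.
#' @export
simulate_bscan <- function(truth, probe, y, seed = 1L, speckle_contrast = 0,
                           overlay = "none", speckle_field = NULL) {
  ysv <- volume_axis(truth, 2)
  if (y < min(ysv) - 1e-9 || y > max(ysv) + 1e-9)
    stop_invalid("elevation y = ", y, " outside truth extent [",
                 min(ysv), ", ", max(ysv), "] mm")
  xs <- volume_axis(truth, 1)
  zs <- volume_axis(truth, 3)
  i <- findInterval(y, ysv, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(ysv) - 1L)
  w <- (y - ysv[i]) / (ysv[i + 1] - ysv[i])
  w <- min(max(w, 0), 1)
  plane <- (1 - w) * truth$intensity[, i, ] + w * truth$intensity[, i + 1, ]
  # plane is (x, z); frames are stored [z, x]
  vz <- truth$voxel_spacing[3]; vx <- truth$voxel_spacing[1]
  sector <- probe$sector
  if (is.null(sector)) {
    sp <- probe$pixel_spacing
    fz <- seq(zs[1], zs[length(zs)], by = sp[1])
    fx <- seq(xs[1], xs[length(xs)], by = sp[2])
    qr <- rep(1 + (fx - xs[1]) / vx, each = length(fz))   # plane rows = x
    qc <- rep(1 + (fz - zs[1]) / vz, times = length(fx))
    vals <- interp_bilinear(plane, qr, qc)$values
    img <- matrix(vals, length(fz), length(fx))
    sig_r <- fwhm_to_sigma(probe$psf_axial_fwhm) / sp[1]
    sig_c <- fwhm_to_sigma(probe$psf_lateral_fwhm) / sp[2]
    origin <- c(x = xs[1], z = zs[1])
    spacing <- sp
  } else {
    nrw <- sector$samples_per_ray; ncl <- sector$rays_per_frame
    pp <- pixel_to_physical(rep(seq_len(nrw), times = ncl),
                            rep(seq_len(ncl), each = nrw),
                            sector, c(nrw, ncl))
    cx <- (xs[1] + xs[length(xs)]) / 2
    qx <- 1 + (pp$x + cx - xs[1]) / vx
    qz <- 1 + (pp$z - zs[1]) / vz
    vals <- interp_bilinear(plane, qx, qz)$values
    img <- matrix(vals, nrw, ncl)
    dr <- (sector$radial_max - sector$radial_min) / (nrw - 1)
    r_mid <- (sector$radial_max + sector$radial_min) / 2
    dlat <- r_mid * (sector$angular_span * pi / 180) / (ncl - 1)
    sig_r <- fwhm_to_sigma(probe$psf_axial_fwhm) / dr
    sig_c <- fwhm_to_sigma(probe$psf_lateral_fwhm) / dlat
    origin <- c(x = xs[1], z = zs[1])  # nominal; polar frames use sector
    spacing <- c(dr, dlat)
  }
  img <- blur_separable(img, sig_r, sig_c)
  if (speckle_contrast > 0) {
    sp_field <- if (!is.null(speckle_field)) speckle_field
                else with_seed(seed, matrix(rayleigh_unit(length(img)),
                                            nrow(img), ncol(img)))
    img <- img * ((1 - speckle_contrast) + speckle_contrast * sp_field)
  }
  img <- pmin(pmax(img * 255, 0), 255)
  om <- NULL
  if (overlay != "none") {
    co <- compose_overlay(img, overlay)
    img <- co$image
    om <- co$mask
  }
  fr <- bscan_frame(img, pixel_spacing = spacing, timestamp = 0,
                    origin = origin)
  attr(fr, "sector") <- sector
  attr(fr, "overlay_mask") <- om
  fr
}

#' Simulate a full screen-captured sweep
#'
#' Generates the container-rate frame sequence a screen capture would
#' record during a constant-speed linear sweep over the phantom: the
#' underlying B-scan content refreshes at the probe's native frame rate
#' (container frames between refreshes are exact duplicates), per-frame
#' cumulative drift is applied on top of the clean content, and the
#' overlay is composited last. Alongside the corrupted sequence, a
#' ground-truth bundle carries everything tests need: the clean distinct
#' frames, true slice positions, the drift schedule, and the overlay mask.
#'
#' @param truth An [us_volume()] ground-truth phantom.
#' @param config A [sweep_sim_config()].
#' @return List with `sequence` (a [frame_sequence()] at container rate)
#'   and `bundle` (list: `clean_frames`, `positions`, `content_index`,
#'   `drift` data.frame, `overlay_mask`, `config`).
#' @export
simulate_sweep <- function(truth, config) {
  probe <- config$probe; sweep <- config$sweep
  n_cont <- floor(config$container_rate * sweep$duration + 1e-9)
  if (n_cont < 1) stop_invalid("sweep shorter than one container frame")
  k <- 0:(n_cont - 1)
  content <- floor(k * probe$native_frame_rate / config$container_rate)
  distinct <- unique(content)
  ys <- config$y_start +
    slice_position(distinct, sweep, probe$native_frame_rate)
  yext <- range(volume_axis(truth, 2))
  if (min(ys) < yext[1] - 1e-9 || max(ys) > yext[2] + 1e-9)
    stop_invalid("sweep extent [", min(ys), ", ", max(ys),
                 "] mm outside truth elevation range")
  clean <- vector("list", length(distinct))
  dirty <- vector("list", length(distinct))
  overlay_mask <- NULL
  cum_dx <- config$drift_per_frame[1] * distinct
  cum_dy <- config$drift_per_frame[2] * distinct
  # elevation-correlated speckle: unit-mean Rayleigh anchor fields every
  # `speckle_decorrelation` mm, linearly blended at each slice elevation,
  # so overlapping beams share their pattern as in a real sweep
  anchor_field <- local({
    cache <- list()
    dims <- NULL
    function(k, dim2) {
      key <- as.character(k)
      if (is.null(cache[[key]])) {
        seed_k <- (config$speckle_seed + 7919 * k) %% 2147483647
        cache[[key]] <<- with_seed(seed_k,
          matrix(rayleigh_unit(prod(dim2)), dim2[1], dim2[2]))
      }
      cache[[key]]
    }
  })
  speckle_for <- function(y, dim2) {
    g <- y / config$speckle_decorrelation
    k0 <- floor(g); w <- g - k0
    (1 - w) * anchor_field(k0, dim2) + w * anchor_field(k0 + 1, dim2)
  }
  frame_dim <- NULL
  for (j in seq_along(distinct)) {
    seed_j <- (config$speckle_seed + 104729 * distinct[j]) %% 2147483647
    field <- NULL
    if (config$speckle_contrast > 0) {
      if (is.null(frame_dim))
        frame_dim <- dim(simulate_bscan(truth, probe, ys[j], seed = 0L))
      field <- speckle_for(ys[j], frame_dim)
    }
    fr <- simulate_bscan(truth, probe, ys[j], seed = seed_j,
                         speckle_contrast = config$speckle_contrast,
                         overlay = "none", speckle_field = field)
    clean[[j]] <- fr
    img <- unclass_frame(fr)
    if (cum_dx[j] != 0 || cum_dy[j] != 0)
      img <- shift_image(img, cum_dy[j], cum_dx[j])$image
    if (config$overlay != "none") {
      co <- compose_overlay(img, config$overlay)
      img <- co$image
      overlay_mask <- co$mask
    }
    dirty[[j]] <- img
  }
  frames <- vector("list", n_cont)
  jmap <- match(content, distinct)
  for (kk in seq_len(n_cont)) {
    f0 <- clean[[jmap[kk]]]
    frames[[kk]] <- bscan_frame(dirty[[jmap[kk]]],
                                pixel_spacing = frame_spacing(f0),
                                timestamp = k[kk] / config$container_rate,
                                source_index = kk,
                                origin = frame_origin(f0))
  }
  seqn <- frame_sequence(frames, effective_rate = config$container_rate,
                         probe = probe)
  drift <- data.frame(container_frame = seq_len(n_cont),
                      content_index = content,
                      dx = cum_dx[jmap], dy = cum_dy[jmap])
  list(sequence = seqn,
       bundle = list(clean_frames = clean, positions = ys,
                     content_index = content, drift = drift,
                     overlay_mask = overlay_mask, config = config))
}
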