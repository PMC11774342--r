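# Probe and sweep geometry: the pixel -> physical mapping that undoes the
# sector-scan (fan) distortion, and the elevation position of each slice
# under constant-speed linear actuation.
#
# Coordinate convention (fixed for NIfTI affine construction): right-handed,
# x lateral within a frame, z depth increasing away from the probe face,
# y the elevation (sweep) direction. Pixel/voxel centers sit on integer
# grid coordinates; R's native 1-based indexing is used throughout.

#' Sector (fan) scan geometry
#'
#' Describes the polar sampling grid of a mechanically or electronically
#' swept sector probe: scan lines radiate from a virtual apex located
#' `apex_offset` mm above the first image row, spanning `angular_span`
#' degrees, with samples between `radial_min` and `radial_max` mm from the
#' apex. Row index maps linearly to radius and column index linearly to ray
#' angle.
#'
#' @param apex_offset Distance (mm, >= 0) of the virtual apex above the
#'   first image row.
#' @param angular_span Full fan angle in degrees, in (0, 180).
#' @param radial_min,radial_max Radial sampling range in mm
#'   (0 <= radial_min < radial_max).
#' @param rays_per_frame,samples_per_ray Native polar grid size.
#' @return An object of class `sector_geometry`.
#' @export
sector_geometry <- function(apex_offset = 0, angular_span = 60,
                            radial_min = 0, radial_max = 50,
                            rays_per_frame = 128L, samples_per_ray = 256L) {
  if (angular_span <= 0 || angular_span >= 180)
    stop_invalid("angular_span must be in (0, 180) degrees")
  if (apex_offset < 0) stop_invalid("apex_offset must be >= 0")
  if (radial_min < 0 || radial_min >= radial_max)
    stop_invalid("need 0 <= radial_min < radial_max")
  structure(list(apex_offset = apex_offset, angular_span = angular_span,
                 radial_min = radial_min, radial_max = radial_max,
                 rays_per_frame = as.integer(rays_per_frame),
                 samples_per_ray = as.integer(samples_per_ray)),
            class = "sector_geometry")
}

#' Ultrasound probe specification
#'
#' Acquisition parameters for one probe. When `sector` is `NULL` the probe
#' is treated as a linear array: the in-plane pixel grid is already
#' Cartesian and scan conversion is the identity.
#'
#' @param name Probe identifier.
#' @param center_frequency Center frequency in MHz.
#' @param native_frame_rate Native acquisition rate in frames/s (>= 1);
#'   this is the rate at which distinct B-scan contents are produced, as
#'   opposed to the screen-capture container rate.
#' @param imaging_depth Displayed depth in mm.
#' @param pixel_spacing Length-2 numeric, mm per pixel along (row, col).
#' @param sector Optional [sector_geometry()].
#' @param psf_axial_fwhm,psf_lateral_fwhm Point-spread function full widths
#'   at half maximum, mm (axial = along depth, lateral = across scan lines).
#' @return An object of class `probe_spec`.
#' @export
probe_spec <- function(name, center_frequency, native_frame_rate,
                       imaging_depth, pixel_spacing = c(0.1, 0.1),
                       sector = NULL,
                       psf_axial_fwhm = 0.2, psf_lateral_fwhm = 0.5) {
  vals <- c(center_frequency, imaging_depth, pixel_spacing,
            psf_axial_fwhm, psf_lateral_fwhm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("all physical probe quantities must be positive")
  if (native_frame_rate < 1)
    stop_invalid("native_frame_rate must be >= 1 frames/s")
  if (!is.null(sector) && !inherits(sector, "sector_geometry"))
    stop_invalid("sector must be a sector_geometry or NULL")
  structure(list(name = as.character(name),
                 center_frequency = center_frequency,
                 native_frame_rate = native_frame_rate,
                 imaging_depth = imaging_depth,
                 pixel_spacing = as.numeric(pixel_spacing),
                 sector = sector,
                 psf_axial_fwhm = psf_axial_fwhm,
                 psf_lateral_fwhm = psf_lateral_fwhm),
            class = "probe_spec")
}

#' Linear sweep specification
#'
#' @param speed Actuation speed in mm/s (> 0).
#' @param duration Sweep duration in s (> 0).
#' @param axis Label of the elevation (sweep) direction, default "y".
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(speed = 1, duration = 10, axis = "y") {
  if (speed <= 0 || duration <= 0)
    stop_invalid("sweep speed and duration must be > 0")
  structure(list(speed = speed, duration = duration, axis = axis),
            class = "sweep_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("<probe_spec> %s: %.4g MHz, %g fps native, depth %g mm\n",
              x$name, x$center_frequency, x$native_frame_rate,
              x$imaging_depth))
  cat(sprintf("  pixel spacing %.4g x %.4g mm, PSF %g/%g mm (axial/lateral)\n",
              x$pixel_spacing[1], x$pixel_spacing[2],
              x$psf_axial_fwhm, x$psf_lateral_fwhm))
  if (is.null(x$sector)) cat("  linear array (identity in-plane geometry)\n")
  else cat(sprintf("  sector: %g deg span, apex offset %g mm, r in [%g, %g] mm\n",
                   x$sector$angular_span, x$sector$apex_offset,
                   x$sector$radial_min, x$sector$radial_max))
  invisible(x)
}

#' Read a probe specification from a flat key-value config file
#'
#' The format is `key = value`, one per line, `#` comments allowed. Keys
#' mirror the arguments of [probe_spec()]; sector parameters are given as
#' `sector_apex_offset`, `sector_angular_span`, `sector_radial_min`,
#' `sector_radial_max`, `sector_rays_per_frame`, `sector_samples_per_ray`
#' and the sector is present iff `sector_angular_span` is set.
#'
#' @param path Path to the config file.
#' @return A `probe_spec`.
#' @export
read_probe_config <- function(path) {
  if (!file.exists(path)) stop_invalid("probe config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop_invalid("malformed config line: ", lines[bad][1])
  vals <- vapply(kv, `[`, "", 2)
  names(vals) <- vapply(kv, `[`, "", 1)
  num <- function(key, default = NULL) {
    if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  }
  sector <- NULL
  if ("sector_angular_span" %in% names(vals)) {
    sector <- sector_geometry(
      apex_offset = num("sector_apex_offset", 0),
      angular_span = num("sector_angular_span"),
      radial_min = num("sector_radial_min", 0),
      radial_max = num("sector_radial_max"),
      rays_per_frame = num("sector_rays_per_frame", 128),
      samples_per_ray = num("sector_samples_per_ray", 256))
  }
  probe_spec(name = if ("name" %in% names(vals)) vals[["name"]] else
               basename(path),
             center_frequency = num("center_frequency"),
             native_frame_rate = num("native_frame_rate"),
             imaging_depth = num("imaging_depth"),
             pixel_spacing = c(num("pixel_spacing_row", 0.1),
                               num("pixel_spacing_col", 0.1)),
             sector = sector,
             psf_axial_fwhm = num("psf_axial_fwhm", 0.2),
             psf_lateral_fwhm = num("psf_lateral_fwhm", 0.5))
}

#' Load a shipped probe preset
#'
#' Presets are named after the three probes the pipeline was designed
#' around: `"A12"` (12 MHz ophthalmic B-scan probe, 11 fps effective
#' acquisition), `"AQ20"` (20 MHz annular probe, 8 fps) and `"BiQ"`
#' (handheld CMUT array used with its ophthalmic preset). Only the
#' native frame rates of the A12 and AQ20 are published figures; the
#' remaining parameters are plausible stand-ins recorded in the config
#' files and are meant to be edited to match a specific device.
#'
#' @param name Preset name, case-insensitive.
#' @return A `probe_spec`.
#' @export
probe_preset <- function(name) {
  file <- system.file("extdata", "probes",
                      paste0(tolower(name), ".cfg"), package = "bscan3d")
  if (!nzchar(file))
    stop_invalid("unknown probe preset: ", name,
                 " (available: A12, AQ20, BiQ)")
  read_probe_config(file)
}

#' Map a polar pixel to physical coordinates
#'
#' For a sector geometry, pixel (row, col) of a rows x cols polar frame
#' samples radius `r = radial_min + (row-1)/(rows-1) * (radial_max -
#' radial_min)` at ray angle `theta = ((col-1)/(cols-1) - 1/2) *
#' angular_span`; its Cartesian position is `x = r sin(theta)`,
#' `z = r cos(theta) - apex_offset`. Indices are 1-based and vectorized.
#'
#' @param row,col Pixel indices (1-based), vectors allowed.
#' @param geom A [sector_geometry()].
#' @param grid_shape Integer length-2: (rows, cols) of the polar frame.
#' @return A list with numeric vectors `x` (mm lateral) and `z` (mm depth).
#' @export
pixel_to_physical <- function(row, col, geom, grid_shape) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  if (rows < 2 || cols < 2)
    stop_invalid("degenerate grid: need at least 2 rows and 2 columns")
  if (any(row < 1 | row > rows) || any(col < 1 | col > cols))
    stop_invalid("pixel index out of range")
  r <- geom$radial_min + (row - 1) / (rows - 1) *
    (geom$radial_max - geom$radial_min)
  theta <- ((col - 1) / (cols - 1) - 0.5) * geom$angular_span * pi / 180
  list(x = r * sin(theta), z = r * cos(theta) - geom$apex_offset)
}

#' Scan-convert a polar (sector) frame onto a Cartesian grid
#'
#' Resamples a frame whose rows/columns index radius/ray-angle onto a
#' regular Cartesian (x, z) grid, undoing the fan distortion that makes
#' flat reflectors appear curved in the raw line-by-line display. Each
#' output pixel takes the bilinear interpolation of the polar source at its
#' inverse-mapped (r, theta); pixels outside the fan are 0 and flagged in
#' the frame's validity mask.
#'
#' When `geom` is `NULL` the mapping is the identity: the frame is returned
#' unchanged (or bilinearly resampled if `out_spacing` differs from its
#' pixel spacing).
#'
#' @param frame A [bscan_frame()].
#' @param geom A [sector_geometry()] or `NULL`.
#' @param out_spacing Output pixel size in mm (scalar or (row, col) pair).
#' @return A Cartesian `bscan_frame` with attributes `origin` (x, z of the
#'   first pixel center, mm) and `valid` (logical matrix).
#' @export
scan_convert <- function(frame, geom, out_spacing) {
  if (any(out_spacing <= 0)) stop_invalid("out_spacing must be > 0")
  out_spacing <- rep_len(as.numeric(out_spacing), 2L)
  img <- unclass_frame(frame)
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(geom)) {
    sp <- frame_spacing(frame)
    if (isTRUE(all.equal(sp, out_spacing))) return(frame)
    new_nr <- max(2L, round((nr - 1) * sp[1] / out_spacing[1]) + 1L)
    new_nc <- max(2L, round((nc - 1) * sp[2] / out_spacing[2]) + 1L)
    qr <- rep(1 + (seq_len(new_nr) - 1) * out_spacing[1] / sp[1], times = new_nc)
    qc <- rep(1 + (seq_len(new_nc) - 1) * out_spacing[2] / sp[2], each = new_nr)
    res <- interp_bilinear(img, qr, qc)
    out <- matrix(res$values, new_nr, new_nc)
    return(bscan_frame(out, pixel_spacing = out_spacing,
                       timestamp = frame_timestamp(frame),
                       source_index = frame_source_index(frame),
                       origin = frame_origin(frame),
                       valid = matrix(res$valid, new_nr, new_nc)))
  }
  if (nr != 2 && nr != geom$samples_per_ray) {
    # tolerate frames whose stored size differs from the nominal polar grid
    geom$samples_per_ray <- nr
  }
  half <- geom$angular_span / 2 * pi / 180
  x_max <- geom$radial_max * sin(half)
  z_min <- geom$radial_min * cos(half) - geom$apex_offset
  z_max <- geom$radial_max - geom$apex_offset
  xs <- seq(-x_max, x_max, by = out_spacing[2])
  zs <- seq(z_min, z_max, by = out_spacing[1])
  nz <- length(zs); nx <- length(xs)
  Z <- matrix(zs, nz, nx) + geom$apex_offset
  X <- matrix(xs, nz, nx, byrow = TRUE)
  r <- sqrt(X^2 + Z^2)
  theta <- atan2(X, Z)
  qrow <- 1 + (r - geom$radial_min) / (geom$radial_max - geom$radial_min) * (nr - 1)
  qcol <- 1 + (theta / (geom$angular_span * pi / 180) + 0.5) * (nc - 1)
  inside <- r >= geom$radial_min & r <= geom$radial_max & abs(theta) <= half
  res <- interp_bilinear(img, as.vector(qrow), as.vector(qcol))
  out <- matrix(res$values, nz, nx)
  valid <- matrix(res$valid, nz, nx) & inside
  out[!valid] <- 0
  bscan_frame(out, pixel_spacing = out_spacing,
              timestamp = frame_timestamp(frame),
              source_index = frame_source_index(frame),
              origin = c(x = -x_max, z = z_min),
              valid = valid)
}

#' Elevation position of a frame under constant-speed actuation
#'
#' Frame `i` (counted from 0 at the start of the sweep) of a sequence
#' acquired at `effective_rate` frames/s during a sweep at `sweep$speed`
#' mm/s lies at elevation `y = speed * i / effective_rate` mm.
#'
#' @param frame_index Frame offset(s) from sweep start, 0-based, >= 0.
#' @param sweep A [sweep_spec()].
#' @param effective_rate Distinct-content frame rate, frames/s (> 0).
#' @return Elevation position(s) in mm.
#' @export
slice_position <- function(frame_index, sweep, effective_rate) {
  if (any(frame_index < 0)) stop_invalid("frame_index must be >= 0")
  if (effective_rate <= 0) stop_invalid("effective_rate must be > 0")
  sweep$speed * frame_index / effective_rate
}
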