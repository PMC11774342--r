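# Regular 3D intensity volume and its NIfTI serialization, plus the
# elevation-axis linear interpolation that assembles cleaned, registered,
# Cartesian slices into a volume. Axis order is (x lateral, y elevation,
# z depth) with an RAS diagonal affine.

#' Construct a 3D volume
#'
#' @param intensity 3D numeric array with dimensions (x, y, z) =
#'   (lateral, elevation, depth), at least 2 voxels per axis.
#' @param voxel_spacing mm per voxel along (x, y, z).
#' @param origin World-mm position of voxel (1, 1, 1), default the zero
#'   point.
#' @param provenance Optional named list (probe, sweep parameters,
#'   pipeline settings) carried into the NIfTI description and sidecar.
#' @return An object of class `us_volume`.
#' @export
us_volume <- function(intensity, voxel_spacing, origin = c(0, 0, 0),
                      provenance = list()) {
  intensity <- as.array(intensity)
  if (length(dim(intensity)) != 3 || any(dim(intensity) < 2))
    stop_invalid("volume must be 3D with at least 2 voxels per axis")
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0))
    stop_invalid("voxel_spacing must be 3 positive values")
  if (any(!is.finite(intensity)))
    stop_invalid("volume intensities must be finite")
  structure(list(intensity = intensity,
                 voxel_spacing = as.numeric(voxel_spacing),
                 origin = as.numeric(origin),
                 provenance = provenance),
            class = "us_volume")
}

#' @export
print.us_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<us_volume> %d x %d x %d voxels (x,y,z), %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3],
              x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3]))
  cat(sprintf("  extent %.3g x %.3g x %.3g mm, origin (%.3g, %.3g, %.3g) mm\n",
              (d[1] - 1) * x$voxel_spacing[1], (d[2] - 1) * x$voxel_spacing[2],
              (d[3] - 1) * x$voxel_spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.us_volume <- function(x) dim(x$intensity)

# World-mm coordinates of voxel centers along one axis.
volume_axis <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$intensity)[axis]) - 1) *
    vol$voxel_spacing[axis]
}

#' Stack Cartesian slices into a volume by elevation interpolation
#'
#' Places each frame at its elevation position and fills a regular voxel
#' grid: a voxel at elevation y between consecutive slice positions
#' `y_i <= y <= y_{i+1}` is the linear blend
#' `((y_{i+1} - y) S_i + (y - y_i) S_{i+1}) / (y_{i+1} - y_i)`.
#' Elevations outside `[first, last]` are not extrapolated — the volume
#' extent is clipped to the swept range. In-plane, frames are bilinearly
#' resampled to the target (z, x) spacing when it differs from theirs.
#'
#' @param frames List of Cartesian [bscan_frame()]s, co-registered and of
#'   identical dimensions.
#' @param positions Strictly increasing elevation positions (mm), one per
#'   frame.
#' @param target_spacing mm per voxel along (x, y, z). Default: the frame
#'   pixel spacing in-plane and the median slice gap along y (anisotropic,
#'   faithful to the acquisition).
#' @param provenance Optional provenance list stored on the volume.
#' @return An [us_volume()] whose provenance carries a `valid` mask array
#'   (intersection of the frames' validity masks, interpolated like the
#'   intensities and thresholded at 0.999).
#' @export
stack_slices <- function(frames, positions, target_spacing = NULL,
                         provenance = list()) {
  n <- length(frames)
  if (n < 2) stop_invalid("need at least 2 frames for an elevation extent")
  if (length(positions) != n) stop_invalid("one position per frame required")
  if (any(diff(positions) <= 0))
    stop_invalid("positions must be strictly increasing")
  sp <- frame_spacing(frames[[1]])
  if (is.null(target_spacing))
    target_spacing <- c(sp[2], stats::median(diff(positions)), sp[1])
  if (any(target_spacing <= 0)) stop_invalid("target_spacing must be > 0")

  # in-plane resample if needed (frames are [z, x] matrices)
  resample_needed <- !isTRUE(all.equal(sp, c(target_spacing[3], target_spacing[1])))
  slices <- vector("list", n)
  valids <- vector("list", n)
  for (i in seq_len(n)) {
    f <- frames[[i]]
    if (resample_needed) {
      f2 <- scan_convert(f, NULL, c(target_spacing[3], target_spacing[1]))
      slices[[i]] <- unclass_frame(f2)
      valids[[i]] <- frame_valid(f2) &
        matrix(interp_bilinear(frame_valid(f) * 1,
               rep(1 + (seq_len(nrow(f2)) - 1) * target_spacing[3] / sp[1], ncol(f2)),
               rep(1 + (seq_len(ncol(f2)) - 1) * target_spacing[1] / sp[2], each = nrow(f2)))$values >= 0.999,
               nrow(f2), ncol(f2))
    } else {
      slices[[i]] <- unclass_frame(f)
      valids[[i]] <- frame_valid(f)
    }
  }
  nzr <- nrow(slices[[1]]); nxr <- ncol(slices[[1]])
  ys <- seq(positions[1], positions[n], by = target_spacing[2])
  ny <- length(ys)
  if (ny < 2) stop_invalid("elevation extent shorter than one voxel")
  vol <- array(0, c(nxr, ny, nzr))
  msk <- array(FALSE, c(nxr, ny, nzr))
  idx <- findInterval(ys, positions, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n - 1L)
  for (iy in seq_len(ny)) {
    i <- idx[iy]
    w <- (ys[iy] - positions[i]) / (positions[i + 1] - positions[i])
    w <- min(max(w, 0), 1)
    S <- (1 - w) * slices[[i]] + w * slices[[i + 1]]
    V <- valids[[i]] & valids[[i + 1]]
    vol[, iy, ] <- t(S)
    msk[, iy, ] <- t(V)
  }
  f1 <- frames[[1]]
  org <- frame_origin(f1)
  provenance$valid <- msk
  us_volume(vol, voxel_spacing = target_spacing,
            origin = c(org["x"], positions[1], org["z"]),
            provenance = provenance)
}

#' Write a volume as NIfTI-1
#'
#' Stores the intensity grid with a diagonal RAS affine encoding the voxel
#' spacing and world origin; textual provenance goes into the header
#' description field (truncated to its 79-byte capacity) and, in full, into
#' an optional JSON sidecar. The validity mask, when present, is written
#' alongside as `<path stem>_mask.nii(.gz)`.
#'
#' @param vol An [us_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param sidecar Write `<path stem>.json` with full provenance
#'   (default TRUE).
#' @param mask Also write the validity-mask companion volume when the
#'   provenance carries one (default TRUE).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar = TRUE, mask = TRUE) {
  if (!inherits(vol, "us_volume")) stop_invalid("not a us_volume")
  if (any(vol$voxel_spacing <= 0))
    stop_invalid("invalid volume: voxel spacing must be positive")
  desc <- paste0("bscan3d",
                 if (!is.null(vol$provenance$probe))
                   paste0(" ", vol$provenance$probe))
  img <- RNifti::asNifti(vol$intensity)
  RNifti::pixdim(img) <- vol$voxel_spacing
  aff <- diag(c(vol$voxel_spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  img$descrip <- substr(desc, 1, 79)
  RNifti::writeNifti(img, path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  if (sidecar) {
    prov <- vol$provenance
    prov$valid <- NULL
    jsonlite::write_json(
      list(voxel_spacing = vol$voxel_spacing, origin = vol$origin,
           dim = dim(vol$intensity), provenance = prov),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (mask && !is.null(vol$provenance$valid)) {
    mimg <- RNifti::asNifti(array(as.integer(vol$provenance$valid),
                                  dim(vol$intensity)))
    RNifti::pixdim(mimg) <- vol$voxel_spacing
    RNifti::sform(mimg) <- structure(aff, code = 2L)
    ext <- if (grepl("\\.gz$", path)) ".nii.gz" else ".nii"
    RNifti::writeNifti(mimg, paste0(stem, "_mask", ext))
  }
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume()]
#'
#' @param path NIfTI path.
#' @return An [us_volume()]; provenance is restored from the JSON sidecar
#'   when present.
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop_invalid("malformed NIfTI file ", path, ": ",
                                 conditionMessage(e)))
  if (length(dim(img)) != 3)
    stop_invalid("malformed volume: header dim is not 3D in ", path)
  sp <- RNifti::pixdim(img)
  if (any(sp <= 0))
    stop_invalid("malformed volume: non-positive pixdim in ", path)
  aff <- RNifti::xform(img)
  prov <- list()
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  sc <- paste0(stem, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$provenance)) prov <- as.list(meta$provenance)
  }
  us_volume(array(as.numeric(img), dim(img)), voxel_spacing = sp,
            origin = aff[1:3, 4], provenance = prov)
}

#' Maximum-intensity en-face projection of a volume
#'
#' Projects along the depth (z) axis, giving the view a clinician would
#' call en face.
#'
#' @param vol An [us_volume()].
#' @return Matrix of dimensions (x, y).
#' @export
enface_projection <- function(vol) {
  nz <- dim(vol$intensity)[3]
  out <- vol$intensity[, , 1]
  for (k in seq_len(nz)[-1]) out <- pmax(out, vol$intensity[, , k])
  out
}
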