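# B-scan frame container and the video_frames stage: extraction from a
# recorded screen capture (as a PNG sequence with a JSON sidecar),
# deduplication of container frames that repeat the same underlying
# acquisition, and lossless round-tripping to disk.

#' Construct a 2D B-scan frame
#'
#' A grayscale echo image with physical pixel spacing and an acquisition
#' timestamp. Intensities live on a 0..`max_level` scale (8-bit by
#' default). The physical position of pixel (i, j) is
#' `z = origin["z"] + (i-1) * pixel_spacing[1]`,
#' `x = origin["x"] + (j-1) * pixel_spacing[2]`.
#'
#' @param intensity Numeric matrix (rows = depth, cols = lateral),
#'   at least 2 x 2.
#' @param pixel_spacing mm per pixel along (row, col).
#' @param timestamp Seconds from sweep start (>= 0).
#' @param source_index Original container frame index, if known.
#' @param max_level Top of the intensity scale (default 255).
#' @param origin Physical (x, z) of the first pixel center in mm; default
#'   centers the lateral axis on the frame and puts z = 0 at the first row.
#' @param valid Optional logical matrix marking pixels that carry data
#'   (used by scan conversion and drift correction).
#' @return An object of class `bscan_frame`.
#' @export
bscan_frame <- function(intensity, pixel_spacing = c(0.1, 0.1),
                        timestamp = 0, source_index = NA_integer_,
                        max_level = 255, origin = NULL, valid = NULL) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) < 2 || ncol(intensity) < 2)
    stop_invalid("frame must be at least 2 x 2")
  if (any(pixel_spacing <= 0)) stop_invalid("pixel_spacing must be > 0")
  if (timestamp < 0) stop_invalid("timestamp must be >= 0")
  rng <- range(intensity, na.rm = TRUE)
  tol <- 1e-6 * max(1, max_level)
  if (rng[1] < -tol || rng[2] > max_level + tol)
    stop_invalid("intensities outside [0, max_level]")
  if (rng[1] < 0 || rng[2] > max_level)  # clamp float dust from resampling
    intensity[] <- pmin(pmax(intensity, 0), max_level)
  if (is.null(origin))
    origin <- c(x = -(ncol(intensity) - 1) / 2 * pixel_spacing[2], z = 0)
  structure(intensity,
            pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
            timestamp = timestamp,
            source_index = source_index,
            max_level = max_level,
            origin = stats::setNames(as.numeric(origin), c("x", "z")),
            valid = valid,
            class = c("bscan_frame", "matrix", "array"))
}

unclass_frame <- function(frame) {
  m <- unclass(frame)
  attributes(m) <- list(dim = dim(m))
  m
}
frame_spacing <- function(frame) attr(frame, "pixel_spacing")
frame_timestamp <- function(frame) attr(frame, "timestamp")
frame_source_index <- function(frame) attr(frame, "source_index")
frame_origin <- function(frame) attr(frame, "origin")
frame_valid <- function(frame) {
  v <- attr(frame, "valid")
  if (is.null(v)) matrix(TRUE, nrow(frame), ncol(frame)) else v
}

#' @export
print.bscan_frame <- function(x, ...) {
  sp <- frame_spacing(x)
  cat(sprintf("<bscan_frame> %d x %d px (%.4g x %.4g mm/px), t = %.4g s\n",
              nrow(x), ncol(x), sp[1], sp[2], frame_timestamp(x)))
  invisible(x)
}

#' Construct an ordered frame sequence
#'
#' @param frames List of [bscan_frame()] with identical dimensions and
#'   spacing and strictly increasing timestamps.
#' @param effective_rate Distinct-content frame rate in frames/s.
#' @param probe Optional [probe_spec()] the frames came from.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, effective_rate, probe = NULL) {
  if (length(frames) == 0) stop_invalid("empty frame list")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) stop_invalid("frames differ in dimensions")
  ts <- vapply(frames, frame_timestamp, 0)
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stop_invalid("timestamps must be strictly increasing")
  if (effective_rate <= 0) stop_invalid("effective_rate must be > 0")
  structure(list(frames = frames, effective_rate = effective_rate,
                 probe = probe),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf("<frame_sequence> %d frames of %d x %d px, %.4g fps effective\n",
              length(x$frames), nrow(f1), ncol(f1), x$effective_rate))
  if (!is.null(x$probe)) cat(sprintf("  probe: %s\n", x$probe$name))
  invisible(x)
}

seq_timestamps <- function(seq) vapply(seq$frames, frame_timestamp, 0)

#' Extract a frame sequence from a recorded source
#'
#' Reads an ordered raster-image sequence: either a directory previously
#' written by [write_frames()] (numbered PNGs plus an `index.json`
#' sidecar), or a character vector of PNG paths. Color sources are
#' converted to grayscale with the standard luma weights
#' (0.299 R + 0.587 G + 0.114 B). Video containers (MP4/AVI) are not
#' decoded directly; export the capture to a PNG sequence first (every
#' common player/ffmpeg can), or register a reader via the same interface.
#'
#' @param source Directory path or character vector of image paths.
#' @param crop_region Optional `c(row0, col0, rows, cols)` (1-based corner)
#'   applied to every frame; must lie within frame bounds.
#' @param container_rate Frames/s of the recording, used for timestamps
#'   when the sidecar does not provide them (default 30).
#' @param pixel_spacing mm/px (row, col) when no sidecar is present.
#' @return A [frame_sequence()] with `effective_rate` initialized to the
#'   container rate.
#' @export
extract_frames <- function(source, crop_region = NULL, container_rate = 30,
                           pixel_spacing = c(0.1, 0.1)) {
  meta <- NULL
  if (length(source) == 1 && dir.exists(source)) {
    idx <- file.path(source, "index.json")
    if (file.exists(idx)) {
      meta <- jsonlite::read_json(idx, simplifyVector = TRUE)
      paths <- file.path(source, meta$files)
    } else {
      paths <- sort(list.files(source, pattern = "\\.png$", full.names = TRUE))
    }
  } else {
    paths <- source
  }
  if (length(paths) == 0) stop_invalid("no frames found in source")
  missing <- !file.exists(paths)
  if (any(missing))
    stop_invalid("unreadable frame source: ", paths[missing][1])
  if (!is.null(meta)) {
    if (!is.null(meta$container_rate)) container_rate <- meta$container_rate
    if (!is.null(meta$pixel_spacing)) pixel_spacing <- meta$pixel_spacing
  }
  ts <- if (!is.null(meta) && !is.null(meta$timestamps)) meta$timestamps
        else (seq_along(paths) - 1) / container_rate
  frames <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    px <- png::readPNG(paths[i])
    if (length(dim(px)) == 3)  # luma conversion for color sources
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    img <- px * 255
    if (!is.null(crop_region)) {
      cr <- as.integer(crop_region)
      r1 <- cr[1]; c1 <- cr[2]; r2 <- r1 + cr[3] - 1L; c2 <- c1 + cr[4] - 1L
      if (r1 < 1 || c1 < 1 || r2 > nrow(img) || c2 > ncol(img))
        stop_invalid("crop_region outside frame bounds (",
                     nrow(img), " x ", ncol(img), ")")
      img <- img[r1:r2, c1:c2, drop = FALSE]
    }
    frames[[i]] <- bscan_frame(img, pixel_spacing = pixel_spacing,
                               timestamp = ts[i], source_index = i)
  }
  frame_sequence(frames, effective_rate = container_rate)
}

#' Write a frame sequence as a numbered PNG sequence with metadata sidecar
#'
#' Frames are stored losslessly as 8-bit grayscale PNGs together with an
#' `index.json` sidecar recording file order, timestamps, pixel spacing,
#' container rate, and probe name, so [extract_frames()] can reconstruct
#' the sequence exactly.
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if needed).
#' @param crop Optional crop record to store in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_frames <- function(seq, dir, crop = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("frame_%05d.png", seq_along(seq$frames))
  for (i in seq_along(seq$frames)) {
    img <- unclass_frame(seq$frames[[i]])
    png::writePNG(round(img) / 255, file.path(dir, files[i]))
  }
  meta <- list(files = files,
               timestamps = seq_timestamps(seq),
               pixel_spacing = frame_spacing(seq$frames[[1]]),
               container_rate = seq$effective_rate,
               probe = if (!is.null(seq$probe)) seq$probe$name else NULL,
               crop = crop)
  jsonlite::write_json(meta, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Collapse duplicated container frames
#'
#' Screen-capture video repeats the last acquired B-scan until the probe
#' produces a new one, so a 30 fps recording of an 11 fps probe carries
#' every frame about three times. Consecutive frames whose mean absolute
#' intensity difference from the last retained frame is at most
#' `tolerance` levels are collapsed, keeping the first frame of each run
#' with its original timestamp. The sequence's `effective_rate` is
#' recomputed as `(retained - 1) / (last - first retained timestamp)`.
#'
#' The tolerance default of 0.5 levels (8-bit scale) absorbs the small
#' pixel perturbations video compression adds to otherwise identical
#' frames; exact byte equality would fail on any lossy capture.
#'
#' @param seq A [frame_sequence()].
#' @param tolerance Mean-absolute-difference threshold in intensity levels.
#' @return A deduplicated [frame_sequence()].
#' @export
deduplicate_frames <- function(seq, tolerance = 0.5) {
  if (length(seq$frames) == 0) stop_invalid("empty sequence")
  if (tolerance < 0) stop_invalid("tolerance must be >= 0")
  keep <- 1L
  anchor <- unclass_frame(seq$frames[[1]])
  for (i in seq_along(seq$frames)[-1]) {
    cur <- unclass_frame(seq$frames[[i]])
    if (mean(abs(cur - anchor)) > tolerance) {
      keep <- c(keep, i)
      anchor <- cur
    }
  }
  frames <- seq$frames[keep]
  ts <- vapply(frames, frame_timestamp, 0)
  rate <- if (length(frames) > 1) (length(frames) - 1) / (ts[length(ts)] - ts[1])
          else seq$effective_rate
  frame_sequence(frames, effective_rate = rate, probe = seq$probe)
}

#' Suggest a crop region containing the echo data
#'
#' Helper for choosing the crop that trims UI chrome from a screen
#' capture: finds the largest rectangular bounding box of pixels whose
#' temporal standard deviation exceeds a small floor (i.e. pixels that
#' actually change as the probe sweeps). The suggestion is never applied
#' automatically.
#'
#' @param seq A [frame_sequence()] (>= 2 frames).
#' @param sd_floor Temporal-SD threshold in levels (default 1).
#' @return `c(row0, col0, rows, cols)` or `NULL` when nothing varies.
#' @export
suggest_crop <- function(seq, sd_floor = 1) {
  st <- temporal_statistics(seq)
  act <- st$sd_image > sd_floor
  if (!any(act)) return(NULL)
  rr <- range(which(rowSums(act) > 0))
  cc <- range(which(colSums(act) > 0))
  c(row0 = rr[1], col0 = cc[1], rows = rr[2] - rr[1] + 1L,
    cols = cc[2] - cc[1] + 1L)
}
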