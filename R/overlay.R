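# Static on-screen annotation (overlay) removal. Screen-captured probe
# video carries scale bars, labels and crosshairs burnt into every frame;
# these are detected as high-intensity pixels whose value is constant
# through the time series — echo speckle decorrelates frame to frame, a
# painted overlay does not.

#' Per-pixel temporal statistics of a frame sequence
#'
#' @param seq A [frame_sequence()] with at least 2 frames.
#' @return An object of class `temporal_stats`: list with `mean_image`,
#'   `sd_image` (population standard deviation) and `n_frames`.
#' @export
temporal_statistics <- function(seq) {
  n <- length(seq$frames)
  if (n < 2) stop_invalid("temporal statistics need at least 2 frames")
  s1 <- unclass_frame(seq$frames[[1]])
  s2 <- s1^2
  for (i in 2:n) {
    f <- unclass_frame(seq$frames[[i]])
    s1 <- s1 + f
    s2 <- s2 + f^2
  }
  mu <- s1 / n
  varp <- pmax(s2 / n - mu^2, 0)  # guard tiny negatives from cancellation
  structure(list(mean_image = mu, sd_image = sqrt(varp), n_frames = n),
            class = "temporal_stats")
}

#' Detect the static-overlay mask
#'
#' Flags pixels that are simultaneously high-intensity (per-pixel temporal
#' mean at or above the `intensity_quantile` quantile of all means) and
#' temporally constant (temporal SD at most `sd_ceiling` levels).
#' Connected components smaller than `min_area` pixels are dropped as
#' speckle coincidences.
#'
#' The thresholds default to the 0.99 mean quantile and 1 level of SD on
#' the 8-bit scale; both are exposed because overlay brightness and
#' capture compression vary across vendors.
#'
#' @param stats A [temporal_statistics()] result.
#' @param intensity_quantile Fraction in (0, 1).
#' @param sd_ceiling Maximum temporal SD, in intensity levels (>= 0).
#' @param min_area Minimum connected-component area in pixels.
#' @return An object of class `overlay_mask`: list with logical `mask`
#'   and `coverage` (fraction of pixels flagged).
#' @export
detect_overlay_mask <- function(stats, intensity_quantile = 0.99,
                                sd_ceiling = 1.0, min_area = 4L) {
  if (intensity_quantile <= 0 || intensity_quantile >= 1)
    stop_invalid("intensity_quantile must be in (0, 1)")
  if (sd_ceiling < 0) stop_invalid("sd_ceiling must be >= 0")
  mu <- stats$mean_image
  if (max(mu) == min(mu)) {
    # a spatially constant image has no "high-intensity" pixels to flag
    warning("degenerate statistics: image is spatially constant, ",
            "returning an empty mask")
    return(structure(list(mask = matrix(FALSE, nrow(mu), ncol(mu)),
                          coverage = 0), class = "overlay_mask"))
  }
  thr <- stats::quantile(mu, intensity_quantile, names = FALSE)
  mask <- mu >= thr & stats$sd_image <= sd_ceiling
  if (any(mask) && min_area > 1) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_area)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  structure(list(mask = mask, coverage = mean(mask)), class = "overlay_mask")
}

#' @export
print.overlay_mask <- function(x, ...) {
  cat(sprintf("<overlay_mask> %d x %d px, coverage %.3f%%\n",
              nrow(x$mask), ncol(x$mask), 100 * x$coverage))
  invisible(x)
}

# Fill masked pixels of one frame with the median of unmasked neighbors,
# growing the neighborhood ring by ring until every pixel has support.
fill_masked_median <- function(img, mask) {
  nr <- nrow(img); nc <- ncol(img)
  filled <- img
  filled[mask] <- NA_real_
  todo <- which(is.na(filled))
  radius <- 1L
  while (length(todo) > 0 && radius <= max(nr, nc)) {
    offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
    offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
    rows <- ((todo - 1L) %% nr) + 1L
    cols <- ((todo - 1L) %/% nr) + 1L
    vals <- matrix(NA_real_, length(todo), nrow(offs))
    for (k in seq_len(nrow(offs))) {
      rr <- rows + offs$dr[k]; cc <- cols + offs$dc[k]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      idx <- (cc - 1L) * nr + rr
      v <- rep(NA_real_, length(todo))
      v[ok] <- img[idx[ok]]
      v[ok][mask[idx[ok]]] <- NA_real_  # only unmasked pixels contribute
      vals[, k] <- v
    }
    med <- apply(vals, 1, stats::median, na.rm = TRUE)
    got <- is.finite(med)
    filled[todo[got]] <- med[got]
    todo <- todo[!got]
    radius <- radius * 2L
  }
  filled[!is.finite(filled)] <- 0
  filled
}

#' Remove the overlay from every frame
#'
#' Replaces masked pixels according to `fill`; unmasked pixels are
#' bit-identical to the input. The default fill is the local median of
#' unmasked neighbors within a growing window, which reconstructs
#' plausible speckle under thin annotations; `"zero"` simply blanks them.
#'
#' @param seq A [frame_sequence()].
#' @param mask An [detect_overlay_mask()] result (or logical matrix).
#' @param fill `"median"` (default) or `"zero"`.
#' @return The cleaned [frame_sequence()].
#' @export
remove_overlay <- function(seq, mask, fill = c("median", "zero")) {
  fill <- match.arg(fill)
  m <- if (inherits(mask, "overlay_mask")) mask$mask else mask
  f1 <- seq$frames[[1]]
  if (!all(dim(m) == dim(f1)))
    stop_invalid("mask dimensions do not match frames")
  if (mean(m) >= 0.5)
    stop_invalid("mask covers >= 50% of the frame; refusing to inpaint ",
                 "(check detection thresholds)")
  if (!any(m)) return(seq)
  frames <- seq$frames
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    img <- unclass_frame(f)
    out <- if (fill == "zero") { img[m] <- 0; img }
           else fill_masked_median(img, m)
    frames[[i]] <- bscan_frame(out, pixel_spacing = frame_spacing(f),
                               timestamp = frame_timestamp(f),
                               source_index = frame_source_index(f),
                               max_level = attr(f, "max_level"),
                               origin = frame_origin(f),
                               valid = attr(f, "valid"))
  }
  frame_sequence(frames, effective_rate = seq$effective_rate,
                 probe = seq$probe)
}

#' Export an overlay mask as a PNG image
#'
#' @param mask An `overlay_mask` (or logical matrix).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_mask <- function(mask, path) {
  m <- if (inherits(mask, "overlay_mask")) mask$mask else mask
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}
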