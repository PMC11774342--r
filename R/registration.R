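# Inter-frame drift registration. Sequential B-scan frames of a linear
# sweep differ mainly by slow in-plane drift of the probe; "linear
# registration" is implemented as translation-only alignment by normalized
# cross-correlation, with optional subpixel refinement of the correlation
# peak. Rotation/scale are deliberately not estimated: they are unobserved
# in this acquisition and fitting them to speckle overfits.

#' In-plane translation between two frames
#'
#' `transform2d(dx, dy)` maps a *moving* frame onto its *reference*:
#' applying it shifts the moving frame by `dx` columns and `dy` rows.
#'
#' @param dx,dy Column and row shift in pixels.
#' @param score Registration confidence in [0, 1] (peak normalized
#'   cross-correlation, clamped at 0).
#' @return An object of class `transform2d`.
#' @export
transform2d <- function(dx = 0, dy = 0, score = 1) {
  if (!all(is.finite(c(dx, dy, score))))
    stop_invalid("transform components must be finite")
  structure(list(dx = dx, dy = dy, score = score), class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d> dx = %+.3f px, dy = %+.3f px (score %.3f)\n",
              x$dx, x$dy, x$score))
  invisible(x)
}

# Band-pass copy used for correlation: the high-pass removes DC and
# low-frequency bias (bright overlays, depth-gain ramps) that would pin
# the peak; the mild low-pass tames speckle pixel-locking so the
# subpixel parabola fit is unbiased.
bandpass_for_registration <- function(img, sigma_lo = 1, sigma_hi = 8) {
  blur_separable(img, sigma_lo, sigma_lo) -
    blur_separable(img, sigma_hi, sigma_hi)
}

# NCC between the central block of `moving` and same-sized blocks of
# `reference` over integer offsets (dy, dx) in [-m, m]^2. Returns the
# (2m+1) x (2m+1) correlation surface indexed [dy + m + 1, dx + m + 1].
ncc_surface <- function(reference, moving, m) {
  nr <- nrow(moving); nc <- ncol(moving)
  rb <- (1 + m):(nr - m); cb <- (1 + m):(nc - m)
  B <- moving[rb, cb]
  B <- B - mean(B)
  bn <- sqrt(sum(B^2))
  surf <- matrix(-1, 2 * m + 1, 2 * m + 1)
  for (dy in -m:m) {
    for (dx in -m:m) {
      R <- reference[rb + dy, cb + dx]
      R <- R - mean(R)
      rn <- sqrt(sum(R^2))
      surf[dy + m + 1, dx + m + 1] <-
        if (bn > 0 && rn > 0) sum(B * R) / (bn * rn) else 0
    }
  }
  surf
}

# 3-point interpolation of the correlation peak position, clamped to half
# a pixel so a flat/degenerate surface cannot throw the estimate. The fit
# is quadratic in log(NCC) when all three samples are positive — the peak
# of a correlation of band-limited texture is locally Gaussian, and the
# log fit removes most of the pixel-locking bias of a plain parabola —
# falling back to the plain parabola otherwise.
parabolic_offset <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    cm <- log(cm); c0 <- log(c0); cp <- log(cp)
  }
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (cm - cp) / den
  max(-0.5, min(0.5, off))
}

#' Register a sequential frame pair
#'
#' Finds the translation that, applied to `moving`, maximizes the
#' normalized cross-correlation with `reference` over integer shifts
#' within `max_shift`, searching a 2-level coarse-to-fine pyramid for
#' large windows. Correlation is computed on high-pass filtered copies so
#' static overlays and DC bias do not dominate. With `subpixel = TRUE`
#' the integer peak is refined by a separable quadratic fit.
#'
#' A low returned `score` (below ~0.2) indicates the frames share no
#' coherent structure (e.g. pure noise); the transform is still returned
#' and the caller decides whether to trust it.
#'
#' @param reference,moving [bscan_frame()]s (or matrices) of identical
#'   dimensions.
#' @param max_shift Search radius in pixels; default 10% of the smaller
#'   frame dimension. Must be < min(dim)/2.
#' @param subpixel Refine the peak to subpixel precision (default TRUE).
#' @return A [transform2d()] mapping `moving` onto `reference`.
#' @export
register_pair <- function(reference, moving, max_shift = NULL,
                          subpixel = TRUE) {
  R <- if (inherits(reference, "bscan_frame")) unclass_frame(reference) else as.matrix(reference)
  M <- if (inherits(moving, "bscan_frame")) unclass_frame(moving) else as.matrix(moving)
  if (!all(dim(R) == dim(M)))
    stop_invalid("reference and moving frames differ in dimensions")
  mindim <- min(dim(R))
  if (is.null(max_shift)) max_shift <- max(2L, round(0.1 * mindim))
  m <- as.integer(ceiling(max_shift))
  if (m >= mindim / 2) stop_invalid("max_shift must be < min(dimensions)/2")
  Rf <- bandpass_for_registration(R)
  Mf <- bandpass_for_registration(M)
  if (m > 4 && mindim >= 8 * 4) {
    # coarse search on 4x block means, then +-2 px refinement at full res
    f <- 4L
    mc <- min(ceiling(m / f), (min(dim(R)) %/% f) %/% 2 - 1)
    cs <- ncc_surface(downsample_mean(Rf, f), downsample_mean(Mf, f), mc)
    pk <- arrayInd(which.max(cs), dim(cs))
    cy <- (pk[1] - mc - 1) * f; cx <- (pk[2] - mc - 1) * f
    w <- 2L + f %/% 2L
    dys <- max(-m, cy - w):min(m, cy + w)
    dxs <- max(-m, cx - w):min(m, cx + w)
  } else {
    dys <- -m:m; dxs <- -m:m
  }
  rb <- (1 + m):(nrow(M) - m); cb <- (1 + m):(ncol(M) - m)
  B <- Mf[rb, cb]; B <- B - mean(B); bn <- sqrt(sum(B^2))
  surf <- matrix(-1, length(dys), length(dxs))
  for (iy in seq_along(dys)) for (ix in seq_along(dxs)) {
    Rb <- Rf[rb + dys[iy], cb + dxs[ix]]
    Rb <- Rb - mean(Rb); rn <- sqrt(sum(Rb^2))
    surf[iy, ix] <- if (bn > 0 && rn > 0) sum(B * Rb) / (bn * rn) else 0
  }
  pk <- arrayInd(which.max(surf), dim(surf))
  dy <- dys[pk[1]]; dx <- dxs[pk[2]]
  score <- surf[pk[1], pk[2]]
  if (subpixel) {
    at <- function(iy, ix) {
      if (iy >= 1 && iy <= nrow(surf) && ix >= 1 && ix <= ncol(surf))
        surf[iy, ix] else NA_real_
    }
    cym <- at(pk[1] - 1, pk[2]); cyp <- at(pk[1] + 1, pk[2])
    cxm <- at(pk[1], pk[2] - 1); cxp <- at(pk[1], pk[2] + 1)
    if (all(is.finite(c(cym, cyp))))
      dy <- dy + parabolic_offset(cym, score, cyp)
    if (all(is.finite(c(cxm, cxp))))
      dx <- dx + parabolic_offset(cxm, score, cxp)
    dy <- max(-max_shift, min(max_shift, dy))
    dx <- max(-max_shift, min(max_shift, dx))
  }
  transform2d(dx = dx, dy = dy, score = max(0, min(1, score)))
}

#' Accumulate pairwise transforms into per-frame drift
#'
#' Pairwise transform `i` maps frame `i+1` onto frame `i`; the cumulative
#' transform for frame `i` (relative to frame 1) is the sum of the first
#' `i-1` pairwise translations, with the identity for frame 1.
#'
#' @param pairwise List of [transform2d()] of length N-1 for N frames
#'   (empty list allowed: yields a single identity).
#' @return List of N cumulative [transform2d()].
#' @export
accumulate_drift <- function(pairwise) {
  n <- length(pairwise) + 1L
  out <- vector("list", n)
  out[[1]] <- transform2d(0, 0, 1)
  dx <- 0; dy <- 0
  for (i in seq_along(pairwise)) {
    p <- pairwise[[i]]
    dx <- dx + p$dx; dy <- dy + p$dy
    out[[i + 1]] <- transform2d(dx, dy, p$score)
  }
  out
}

#' Apply cumulative drift correction to a sequence
#'
#' Resamples each frame by its cumulative translation (bilinear for
#' fractional shifts; exact copy for integer shifts). Border pixels
#' exposed by the shift are filled with 0 and removed from the frame's
#' validity mask. Dimensions and timestamps are unchanged.
#'
#' @param seq A [frame_sequence()].
#' @param cumulative List of [transform2d()], one per frame.
#' @return The corrected [frame_sequence()].
#' @export
apply_drift_correction <- function(seq, cumulative) {
  if (length(cumulative) != length(seq$frames))
    stop_invalid("need exactly one transform per frame")
  frames <- seq$frames
  for (i in seq_along(frames)) {
    tr <- cumulative[[i]]
    if (tr$dx == 0 && tr$dy == 0) next
    f <- frames[[i]]
    sh <- shift_image(unclass_frame(f), tr$dy, tr$dx)
    frames[[i]] <- bscan_frame(sh$image, pixel_spacing = frame_spacing(f),
                               timestamp = frame_timestamp(f),
                               source_index = frame_source_index(f),
                               max_level = attr(f, "max_level"),
                               origin = frame_origin(f),
                               valid = frame_valid(f) & sh$valid)
  }
  frame_sequence(frames, effective_rate = seq$effective_rate,
                 probe = seq$probe)
}

#' Estimate drift over a whole sequence
#'
#' Convenience wrapper: registers every sequential pair and accumulates
#' the results.
#'
#' @inheritParams register_pair
#' @param seq A [frame_sequence()].
#' @return List with `pairwise`, `cumulative` (lists of [transform2d()])
#'   and `table` (data.frame frame/dx/dy/score of cumulative drift,
#'   suitable for QC export via [utils::write.table()]).
#' @export
estimate_drift <- function(seq, max_shift = NULL, subpixel = TRUE) {
  n <- length(seq$frames)
  pairwise <- vector("list", max(0L, n - 1L))
  for (i in seq_len(n - 1L))
    pairwise[[i]] <- register_pair(seq$frames[[i]], seq$frames[[i + 1]],
                                   max_shift = max_shift, subpixel = subpixel)
  cumulative <- accumulate_drift(pairwise)
  tab <- data.frame(frame = seq_len(n),
                    dx = vapply(cumulative, `[[`, 0, "dx"),
                    dy = vapply(cumulative, `[[`, 0, "dy"),
                    score = vapply(cumulative, `[[`, 0, "score"))
  list(pairwise = pairwise, cumulative = cumulative, table = tab)
}
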