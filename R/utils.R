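# Internal numerical helpers shared across the pipeline stages.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global random-number state so that seeded
#' simulation calls do not disturb the caller's stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Bilinear interpolation of a 2D image at fractional positions
#'
#' @param img Numeric matrix.
#' @param r,c Numeric vectors of 1-based (fractional) row/column query
#'   positions, recycled to a common length.
#' @param fill Value returned for queries outside the image.
#' @return A list with `values` (numeric vector) and `valid` (logical vector,
#'   FALSE where the query fell outside the image support).
#' @keywords internal
interp_bilinear <- function(img, r, c, fill = 0) {
  n <- max(length(r), length(c))
  r <- rep_len(as.numeric(r), n)
  c <- rep_len(as.numeric(c), n)
  nr <- nrow(img); nc <- ncol(img)
  # tolerate float rounding at the grid border (seq() overshoot)
  eps <- 1e-6
  valid <- r >= 1 - eps & r <= nr + eps & c >= 1 - eps & c <= nc + eps &
    is.finite(r) & is.finite(c)
  out <- rep(fill, n)
  if (any(valid)) {
    rv <- pmin(pmax(r[valid], 1), nr)
    cv <- pmin(pmax(c[valid], 1), nc)
    r0 <- pmin(floor(rv), nr - 1L); c0 <- pmin(floor(cv), nc - 1L)
    fr <- rv - r0; fc <- cv - c0
    i00 <- r0 + (c0 - 1) * nr
    v <- (1 - fr) * (1 - fc) * img[i00] +
         fr       * (1 - fc) * img[i00 + 1] +
         (1 - fr) * fc       * img[i00 + nr] +
         fr       * fc       * img[i00 + nr + 1]
    out[valid] <- v
  }
  list(values = out, valid = valid)
}

# Dense 1D Gaussian convolution operator (n x n, truncated at 4 sigma,
# renormalized at the borders so constants are preserved).
gaussian_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma))
  offs <- (-half):half
  w <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (k in seq_along(offs)) {
    j <- seq_len(n) + offs[k]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + w[k]
  }
  K / rowSums(K)
}

#' Separable Gaussian blur of a matrix
#'
#' @param img Numeric matrix.
#' @param sigma_row,sigma_col Standard deviations in pixels along rows
#'   (first index) and columns. Zero disables blurring along that axis.
#' @return Blurred matrix of the same dimensions.
#' @keywords internal
blur_separable <- function(img, sigma_row, sigma_col = sigma_row) {
  if (sigma_row > 0) img <- gaussian_conv_matrix(nrow(img), sigma_row) %*% img
  if (sigma_col > 0) img <- img %*% t(gaussian_conv_matrix(ncol(img), sigma_col))
  img
}

# FWHM (in pixels/mm) <-> Gaussian sigma.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Translate an image by a (possibly fractional) shift
#'
#' The output satisfies `out[r, c] = img[r - dy, c - dx]` with bilinear
#' interpolation; pixels pulled from outside the source are set to `fill`
#' and flagged invalid.
#'
#' @param img Numeric matrix.
#' @param dy,dx Row and column components of the translation, in pixels.
#' @param fill Fill value for exposed borders.
#' @return List with `image` and logical `valid` matrix.
#' @keywords internal
shift_image <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (dy == 0 && dx == 0)
    return(list(image = img, valid = matrix(TRUE, nr, nc)))
  if (dy == round(dy) && dx == round(dx)) {
    # integer shifts are exact copies, no interpolation
    out <- matrix(fill, nr, nc)
    valid <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) - dy; cs <- seq_len(nc) - dx
    rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
    if (any(rok) && any(cok)) {
      out[rok, cok] <- img[rs[rok], cs[cok]]
      valid[rok, cok] <- TRUE
    }
    return(list(image = out, valid = valid))
  }
  qr <- rep(seq_len(nr) - dy, times = nc)
  qc <- rep(seq_len(nc) - dx, each = nr)
  res <- interp_bilinear(img, qr, qc, fill = fill)
  list(image = matrix(res$values, nr, nc),
       valid = matrix(res$valid, nr, nc))
}

# Block-mean downsampling by an integer factor (trailing remainder dropped).
downsample_mean <- function(img, f) {
  if (f <= 1) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(img, c(f, nr %/% f, f, nc %/% f))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# Labeled connected components (8-connectivity) of a logical matrix.
label_components <- function(mask) {
  EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

stop_invalid <- function(...) stop(..., call. = FALSE)
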