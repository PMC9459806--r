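# Low-level image sampling and filtering shared by the segmentation,
# optical-flow and particle-filter code. All functions take plain numeric
# matrices mat[row, col] and 0-based (x, y) pixel coordinates.

#' Bilinear image sampling at fractional pixel positions
#'
#' Samples a grayscale image at arbitrary (possibly fractional) positions by
#' bilinear interpolation. Coordinates outside the image are clamped to the
#' border (replicate padding).
#'
#' @param img Numeric matrix `img[row, col]`.
#' @param x,y Numeric vectors of equal length; 0-based pixel coordinates
#'   (`x` = column, `y` = row).
#' @return Numeric vector of sampled intensities, same length as `x`.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img)
  nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  x1 <- pmin(x0 + 1, nc - 1)
  y1 <- pmin(y0 + 1, nr - 1)
  # 1-based linear indices into the matrix
  i00 <- y0 + 1 + nr * x0
  i10 <- y1 + 1 + nr * x0
  i01 <- y0 + 1 + nr * x1
  i11 <- y1 + 1 + nr * x1
  (1 - fx) * ((1 - fy) * img[i00] + fy * img[i10]) +
    fx * ((1 - fy) * img[i01] + fy * img[i11])
}

#' Central-difference image gradients
#'
#' @param img Numeric matrix.
#' @return List with matrices `gx` (d/dx, along columns) and `gy` (d/dy,
#'   along rows), border rows/columns use one-sided differences scaled to
#'   match the central stencil.
#' @keywords internal
image_gradient <- function(img) {
  nr <- nrow(img)
  nc <- ncol(img)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  if (nc >= 3) {
    gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  }
  gx[, 1] <- img[, 2] - img[, 1]
  gx[, nc] <- img[, nc] - img[, nc - 1]
  if (nr >= 3) {
    gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  }
  gy[1, ] <- img[2, ] - img[1, ]
  gy[nr, ] <- img[nr, ] - img[nr - 1, ]
  list(gx = gx, gy = gy)
}

# Separable convolution with a 1D kernel (replicate borders).
conv_sep <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  nr <- nrow(img)
  nc <- ncol(img)
  # pad by replication along rows then columns
  ridx <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  cidx <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  p <- img[ridx, , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) out <- out + k[i] * p[i:(i + nr - 1L), , drop = FALSE]
  p <- out[, cidx, drop = FALSE]
  out2 <- matrix(0, nr, nc)
  for (i in seq_along(k)) out2 <- out2 + k[i] * p[, i:(i + nc - 1L), drop = FALSE]
  out2
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  conv_sep(img, gaussian_kernel_1d(sigma))
}

# Downsample by 2 after a 5-tap binomial blur (image-pyramid step).
pyr_down <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  s <- conv_sep(img, k)
  s[seq(1, nrow(img), by = 2), seq(1, ncol(img), by = 2), drop = FALSE]
}
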