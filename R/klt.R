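# Pyramidal Kanade-Lucas-Tomasi point tracking with forward-backward
# validation. Physical hyperparameters (block size, bidirectional error) are
# stated in mm and converted to pixels through the calibration.

#' KLT point-tracker parameters
#'
#' Defaults follow the published configuration: 5 mm x 5 mm block, 9 pyramid
#' levels, 3 mm maximal bidirectional error, 40 iterations. The pyramid depth
#' is capped automatically so the block still fits at the coarsest level.
#'
#' @param block_size_mm Side of the square integration window, mm.
#' @param pyramid_levels Number of pyramid levels (cap; >= 1).
#' @param max_bidir_error_mm Maximal forward-backward error, mm.
#' @param max_iter Iteration cap per level.
#' @param epsilon Convergence threshold on the per-iteration update, px.
#' @return List of class `klt_params`.
#' @export
klt_params <- function(block_size_mm = 5, pyramid_levels = 9L,
                       max_bidir_error_mm = 3, max_iter = 40L,
                       epsilon = 0.01) {
  stopifnot(block_size_mm > 0, pyramid_levels >= 1, max_iter >= 1)
  structure(list(block_size_mm = block_size_mm,
                 pyramid_levels = as.integer(pyramid_levels),
                 max_bidir_error_mm = max_bidir_error_mm,
                 max_iter = as.integer(max_iter), epsilon = epsilon),
            class = "klt_params")
}

# mm -> px conversion; when no calibration is supplied the stated values are
# interpreted as pixels (with a one-time warning from the caller).
mm_to_px <- function(value_mm, mm_per_pixel) {
  if (is.null(mm_per_pixel) || is.na(mm_per_pixel)) value_mm else value_mm / mm_per_pixel
}

build_pyramid <- function(img, levels, min_size) {
  pyr <- list(img)
  while (length(pyr) < levels &&
         min(dim(pyr[[length(pyr)]])) >= 2 * min_size) {
    pyr[[length(pyr) + 1L]] <- pyr_down(pyr[[length(pyr)]])
  }
  pyr
}

# Single-level iterative LK for one point. Returns c(x, y, converged).
lk_refine <- function(ref, trk, p0, guess, half, max_iter, epsilon) {
  nr <- nrow(ref); nc <- ncol(ref)
  wx <- p0[1] + (-half):half
  wy <- p0[2] + (-half):half
  gx <- rep(wx, each = length(wy))
  gy <- rep(wy, times = length(wx))
  if (p0[1] < 0 || p0[1] > nc - 1 || p0[2] < 0 || p0[2] > nr - 1) {
    return(c(guess, 0))
  }
  tpl <- bilinear_sample(ref, gx, gy)
  # window gradients of the reference patch (sampled with central differences)
  ix <- (bilinear_sample(ref, gx + 0.5, gy) - bilinear_sample(ref, gx - 0.5, gy))
  iy <- (bilinear_sample(ref, gx, gy + 0.5) - bilinear_sample(ref, gx, gy - 0.5))
  gxx <- sum(ix * ix); gxy <- sum(ix * iy); gyy <- sum(iy * iy)
  detg <- gxx * gyy - gxy * gxy
  if (!is.finite(detg) || detg < 1e-10) return(c(guess, 0))
  v <- guess - p0
  converged <- 0
  for (k in seq_len(max_iter)) {
    cur <- bilinear_sample(trk, gx + v[1], gy + v[2])
    e <- cur - tpl
    bx <- sum(ix * e); by <- sum(iy * e)
    dv <- -c(gyy * bx - gxy * by, -gxy * bx + gxx * by) / detg
    v <- v + dv
    if (sqrt(sum(dv^2)) < epsilon) {
      converged <- 1
      break
    }
  }
  c(p0 + v, converged)
}

#' Track points between two frames with pyramidal Lucas-Kanade flow
#'
#' Forward-tracks each point from `ref` to `tracked` through an image
#' pyramid; a point is valid iff the forward track converged in bounds and
#' the backward-tracked position lies within the maximal bidirectional error
#' of the original point.
#'
#' @param ref,tracked [us_frame]s (or matrices) of identical shape.
#' @param points n x 2 matrix of `(x, y)` positions in `ref`.
#' @param params [klt_params()].
#' @param mm_per_pixel Calibration used to convert mm-specified parameters;
#'   taken from `ref` when it is a [us_frame].
#' @return List: `points` (n x 2 new positions), `valid` (logical).
#' @export
track_points <- function(ref, tracked, points, params = klt_params(),
                         mm_per_pixel = NULL) {
  if (inherits(ref, "us_frame")) {
    if (is.null(mm_per_pixel)) mm_per_pixel <- ref$mm_per_pixel
    ref <- ref$pixels
  }
  if (inherits(tracked, "us_frame")) tracked <- tracked$pixels
  stopifnot(identical(dim(ref), dim(tracked)))
  if (is.null(mm_per_pixel)) {
    warning("no calibration supplied; mm-specified KLT parameters interpreted as pixels")
  }
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  if (n < 1L) stop("need at least one point", call. = FALSE)
  block_px <- mm_to_px(params$block_size_mm, mm_per_pixel)
  half <- max(1L, round((block_px - 1) / 2))
  block_odd <- 2L * half + 1L            # nearest odd block size >= 3
  bidir_px <- mm_to_px(params$max_bidir_error_mm, mm_per_pixel)
  pyr_ref <- build_pyramid(ref, params$pyramid_levels, block_odd)
  pyr_trk <- build_pyramid(tracked, params$pyramid_levels, block_odd)
  levels <- min(length(pyr_ref), length(pyr_trk))
  track_one_dir <- function(pa, pb, pts) {
    out <- matrix(NA_real_, nrow(pts), 2)
    conv <- logical(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      p0 <- pts[i, ] / 2^(levels - 1)
      v <- p0
      ok <- 1
      for (lv in levels:1) {
        p_lv <- pts[i, ] / 2^(lv - 1)
        r <- lk_refine(pa[[lv]], pb[[lv]], p_lv, v, half, params$max_iter,
                       params$epsilon)
        ok <- r[3]
        v <- if (lv > 1) r[1:2] * 2 else r[1:2]
      }
      out[i, ] <- v
      conv[i] <- ok > 0
    }
    list(points = out, converged = conv)
  }
  fwd <- track_one_dir(pyr_ref, pyr_trk, points)
  nr <- nrow(ref); nc <- ncol(ref)
  inb <- fwd$points[, 1] >= 0 & fwd$points[, 1] <= nc - 1 &
    fwd$points[, 2] >= 0 & fwd$points[, 2] <= nr - 1
  valid <- fwd$converged & inb & is.finite(rowSums(fwd$points))
  if (any(valid)) {
    bwd <- track_one_dir(pyr_trk, pyr_ref, fwd$points[valid, , drop = FALSE])
    err <- sqrt(rowSums((bwd$points - points[valid, , drop = FALSE])^2))
    valid[valid] <- bwd$converged & is.finite(err) & err <= bidir_px
  }
  list(points = fwd$points, valid = valid)
}
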