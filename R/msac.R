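# Affine motion estimation between point sets by M-estimator sample
# consensus (MSAC): random minimal samples of three correspondences, exact
# affine fit, truncated-quadratic scoring, and a final least-squares refit on
# the inliers of the best model.

#' MSAC parameters
#'
#' @param max_trials Upper bound on random trials (the published setting is
#'   1e6; trials stop early under the standard adaptive rule once an
#'   outlier-free sample has been drawn with confidence `confidence`).
#' @param max_distance_px Inlier threshold: distance between a destination
#'   point and the projection of its source point.
#' @param confidence Adaptive-stopping confidence.
#' @param min_trials Lower bound on trials.
#' @return List of class `msac_params`.
#' @export
msac_params <- function(max_trials = 1e6, max_distance_px = 30,
                        confidence = 0.9999, min_trials = 50L) {
  stopifnot(max_trials >= 1, max_distance_px > 0, confidence > 0, confidence < 1)
  structure(list(max_trials = max_trials, max_distance_px = max_distance_px,
                 confidence = confidence, min_trials = as.integer(min_trials)),
            class = "msac_params")
}

# Exact affine through 3 correspondences; NULL if degenerate (collinear).
affine_from_three <- function(src, dst) {
  A <- cbind(src, 1)
  det3 <- det(A)
  if (!is.finite(det3) || abs(det3) < 1e-6) return(NULL)
  cf <- solve(A, dst)          # 3x2: columns are (a, b, tx) and (c, d, ty)
  rbind(c(cf[1, 1], cf[2, 1], cf[3, 1]),
        c(cf[1, 2], cf[2, 2], cf[3, 2]))
}

# Least-squares affine on >= 3 correspondences.
affine_lsfit <- function(src, dst) {
  A <- cbind(src, 1)
  cf <- qr.solve(A, dst)
  rbind(c(cf[1, 1], cf[2, 1], cf[3, 1]),
        c(cf[1, 2], cf[2, 2], cf[3, 2]))
}

affine_residuals <- function(M, src, dst) {
  proj <- apply_affine(M, src)
  sqrt(rowSums((dst - proj)^2))
}

#' Estimate a 2D affine transform by MSAC
#'
#' Repeatedly samples three correspondences, fits the exact affine, and
#' scores all correspondences with the truncated cost
#' `sum(min(d^2, max_distance^2))`; the lowest-cost model wins and is refit
#' by least squares on its inliers (`d <= max_distance`). The number of
#' trials adapts to the observed inlier ratio up to `max_trials`.
#'
#' @param src,dst Matrices (n x 2) of corresponding `(x, y)` points.
#' @param params [msac_params()].
#' @return List: `transform` (2x3 matrix mapping src to dst), `inliers`
#'   (logical vector), `trials`.
#' @export
estimate_affine_msac <- function(src, dst, params = msac_params()) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  n <- nrow(src)
  if (n != nrow(dst)) stop("src/dst length mismatch", call. = FALSE)
  if (n < 3L) stop("need at least 3 correspondences", call. = FALSE)
  thr2 <- params$max_distance_px^2
  best_cost <- Inf
  best_M <- NULL
  needed <- params$max_trials
  trials <- 0L
  degenerate <- 0L
  while (trials < needed && trials < params$max_trials) {
    trials <- trials + 1L
    idx <- sample.int(n, 3L)
    M <- affine_from_three(src[idx, , drop = FALSE], dst[idx, , drop = FALSE])
    if (is.null(M)) {
      degenerate <- degenerate + 1L
      if (degenerate > 1000L && is.null(best_M)) {
        stop("all MSAC trials degenerate (collinear samples)", call. = FALSE)
      }
      next
    }
    d2 <- affine_residuals(M, src, dst)^2
    cost <- sum(pmin(d2, thr2))
    if (cost < best_cost) {
      best_cost <- cost
      best_M <- M
      w <- mean(d2 <= thr2)
      needed <- if (w >= 1) {
        params$min_trials
      } else {
        max(params$min_trials,
            ceiling(log(1 - params$confidence) / log(1 - max(w, 1e-3)^3)))
      }
    }
  }
  if (is.null(best_M)) stop("MSAC failed: no valid minimal sample", call. = FALSE)
  inl <- affine_residuals(best_M, src, dst) <= params$max_distance_px
  if (sum(inl) >= 3L) {
    M <- affine_lsfit(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
    inl <- affine_residuals(M, src, dst) <= params$max_distance_px
  } else {
    M <- best_M
  }
  if (abs(det(M[, 1:2])) <= 1e-8) stop("degenerate affine estimate", call. = FALSE)
  list(transform = M, inliers = inl, trials = trials)
}

#' Define the fascicle-band region of interest from the insertion points
#'
#' Axis-aligned rectangle spanned by the two insertion points A and B,
#' clipped to the frame.
#'
#' @param A,B Numeric `c(x, y)` points.
#' @param frame_shape Optional `c(rows, cols)` for clipping.
#' @return List of class `roi_rect`: `x`, `y`, `width`, `height` (px,
#'   0-based corner).
#' @export
define_roi <- function(A, B, frame_shape = NULL) {
  if (any(!is.finite(c(A, B)))) stop("non-finite ROI corner", call. = FALSE)
  x0 <- min(A[1], B[1]); x1 <- max(A[1], B[1])
  y0 <- min(A[2], B[2]); y1 <- max(A[2], B[2])
  if (!is.null(frame_shape)) {
    nr <- frame_shape[1]; nc <- frame_shape[2]
    x0 <- max(x0, 0); y0 <- max(y0, 0)
    x1 <- min(x1, nc - 1); y1 <- min(y1, nr - 1)
  }
  if (x1 - x0 <= 0) stop("zero-width ROI", call. = FALSE)
  if (y1 - y0 <= 0) stop("zero-height ROI", call. = FALSE)
  structure(list(x = x0, y = y0, width = x1 - x0, height = y1 - y0),
            class = "roi_rect")
}

#' Map a segment through an affine transform
#'
#' @param line 2x2 matrix (rows = endpoints).
#' @param transform 2x3 affine matrix.
#' @return 2x2 matrix of mapped endpoints.
#' @export
propagate_line <- function(line, transform) {
  out <- apply_affine(transform, as.matrix(line))
  rownames(out) <- rownames(line)
  out
}
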