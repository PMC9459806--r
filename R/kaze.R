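# Interest-point detection in a nonlinear (edge-preserving) diffusion scale
# space, in the spirit of the KAZE detector: variable-conductance diffusion
# with the Weickert "edge" conductivity, a scale-normalised
# determinant-of-Hessian response, and 3D (x, y, scale) non-maximum
# suppression. Detection only -- point correspondence comes from optical
# flow, not descriptor matching.

#' Nonlinear scale-space detector parameters
#'
#' @param n_octaves Number of octaves (> 1); the effective number is capped
#'   so the diffusion scale stays small relative to the ROI.
#' @param n_scale_levels Sublevels per octave, in `[3, 10]`.
#' @param diffusion Conductivity type; `"edge"` is the Weickert conductivity
#'   `g = 1 - exp(-3.315 / (|grad L| / k)^8)`.
#' @param sigma0 Base scale (px).
#' @param kpercentile Percentile of the gradient-magnitude histogram used
#'   for the contrast parameter `k`.
#' @param rel_threshold Response threshold relative to the maximal response.
#' @param max_points Keep at most this many strongest points.
#' @return List of class `kaze_params`.
#' @export
kaze_params <- function(n_octaves = 9L, n_scale_levels = 5L,
                        diffusion = c("edge", "pm2"), sigma0 = 1.6,
                        kpercentile = 0.7, rel_threshold = 1e-3,
                        max_points = 200L) {
  diffusion <- match.arg(diffusion)
  stopifnot(n_octaves > 1, n_scale_levels >= 3, n_scale_levels <= 10)
  structure(list(n_octaves = as.integer(n_octaves),
                 n_scale_levels = as.integer(n_scale_levels),
                 diffusion = diffusion, sigma0 = sigma0,
                 kpercentile = kpercentile, rel_threshold = rel_threshold,
                 max_points = as.integer(max_points)),
            class = "kaze_params")
}

conductivity <- function(L, k, type) {
  g <- image_gradient(gaussian_blur(L, 1))
  mag2 <- g$gx^2 + g$gy^2
  if (type == "edge") {
    # Weickert: g = 1 - exp(-3.315 / (|grad|/k)^8); g = 1 at zero gradient
    r4 <- (mag2 / k^2)^4
    out <- 1 - exp(-3.315 / pmax(r4, 1e-300))
    out[mag2 == 0] <- 1
    out
  } else {
    1 / (1 + mag2 / k^2)
  }
}

# One explicit step of variable-conductance diffusion, replicate borders.
diffusion_step <- function(L, g, dt) {
  nr <- nrow(L); nc <- ncol(L)
  up <- rbind(L[1, ], L[-nr, ]); gup <- rbind(g[1, ], g[-nr, ])
  dn <- rbind(L[-1, ], L[nr, ]); gdn <- rbind(g[-1, ], g[nr, ])
  lf <- cbind(L[, 1], L[, -nc]); glf <- cbind(g[, 1], g[, -nc])
  rt <- cbind(L[, -1], L[, nc]); grt <- cbind(g[, -1], g[, nc])
  L + dt * 0.5 * ((g + gup) * (up - L) + (g + gdn) * (dn - L) +
                    (g + glf) * (lf - L) + (g + grt) * (rt - L))
}

# Second derivatives with a stencil spacing `d` proportional to the scale,
# so responses are comparable across levels without an explicit sigma^4
# factor (which diverges under edge-preserving diffusion, where strong edges
# never blur away).
second_derivatives <- function(L, d = 1L) {
  nr <- nrow(L); nc <- ncol(L)
  pad_r <- function(M) rbind(M[rep(1, d), , drop = FALSE], M, M[rep(nr, d), , drop = FALSE])
  pad_c <- function(M) cbind(M[, rep(1, d), drop = FALSE], M, M[, rep(nc, d), drop = FALSE])
  P <- pad_c(pad_r(L))
  i <- (d + 1):(nr + d); j <- (d + 1):(nc + d)
  lxx <- P[i, j + d] - 2 * P[i, j] + P[i, j - d]
  lyy <- P[i + d, j] - 2 * P[i, j] + P[i - d, j]
  lxy <- (P[i + d, j + d] + P[i - d, j - d] - P[i + d, j - d] - P[i - d, j + d]) / 4
  list(lxx = lxx, lyy = lyy, lxy = lxy)
}

#' Detect interest points in a nonlinear scale space
#'
#' Builds an edge-preserving diffusion scale space over the ROI and returns
#' the scale-normalised determinant-of-Hessian maxima. Deterministic for a
#' fixed input.
#'
#' @param frame [us_frame] or intensity matrix.
#' @param roi A `roi_rect` from [define_roi()] (or NULL for the full frame).
#' @param params [kaze_params()].
#' @return Matrix with columns `x`, `y` (full-frame 0-based coordinates),
#'   `sigma`, `response`, strongest first. Fewer than 3 detected points is
#'   an error ("insufficient texture": the affine minimal set would be
#'   unsatisfiable).
#' @export
detect_kaze <- function(frame, roi = NULL, params = kaze_params()) {
  img <- if (inherits(frame, "us_frame")) frame$pixels else as.matrix(frame)
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(roi)) roi <- structure(list(x = 0, y = 0, width = nc - 1, height = nr - 1),
                                     class = "roi_rect")
  pad <- 8L
  x0 <- max(0L, floor(roi$x) - pad); x1 <- min(nc - 1L, ceiling(roi$x + roi$width) + pad)
  y0 <- max(0L, floor(roi$y) - pad); y1 <- min(nr - 1L, ceiling(roi$y + roi$height) + pad)
  sub <- img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  if (min(dim(sub)) < 16L) stop("ROI too small for scale-space detection", call. = FALSE)
  base <- gaussian_blur(sub, 1)
  gm <- image_gradient(base)
  mag <- sqrt(gm$gx^2 + gm$gy^2)
  k <- stats::quantile(mag[mag > 0], params$kpercentile, names = FALSE)
  if (!is.finite(k) || k <= 0) stop("insufficient texture in ROI", call. = FALSE)
  S <- params$n_scale_levels
  sig_max <- min(dim(sub)) / 8
  sigmas <- c()
  for (o in 0:(params$n_octaves - 1)) {
    for (s in 0:(S - 1)) {
      sg <- params$sigma0 * 2^(o + s / S)
      if (sg > sig_max) break
      sigmas <- c(sigmas, sg)
    }
    if (sg > sig_max) break
  }
  if (length(sigmas) < 3L) sigmas <- params$sigma0 * 2^(seq(0, 1, length.out = 4))
  times <- sigmas^2 / 2
  dt <- 0.25
  L <- base
  tcur <- params$sigma0^2 / 2
  levels <- vector("list", length(sigmas))
  g <- conductivity(L, k, params$diffusion)
  for (i in seq_along(sigmas)) {
    nsteps <- max(0L, ceiling((times[i] - tcur) / dt))
    for (n in seq_len(nsteps)) {
      # conductivity refreshed every few steps; the image changes slowly
      if (n %% 4L == 1L) g <- conductivity(L, k, params$diffusion)
      step <- min(dt, times[i] - tcur)
      L <- diffusion_step(L, g, step)
      tcur <- tcur + step
    }
    levels[[i]] <- L
  }
  resp <- vector("list", length(sigmas))
  for (i in seq_along(sigmas)) {
    d <- second_derivatives(levels[[i]], max(1L, round(sigmas[i] / 2)))
    resp[[i]] <- d$lxx * d$lyy - d$lxy^2
  }
  rmax <- max(vapply(resp, max, numeric(1)))
  thr <- max(1e-7, params$rel_threshold * rmax)
  pts <- NULL
  nrs <- nrow(sub); ncs <- ncol(sub)
  for (i in seq_along(sigmas)) {
    R <- resp[[i]]
    cand <- which(R > thr)
    if (length(cand) == 0) next
    rr <- ((cand - 1) %% nrs) + 1
    cc <- ((cand - 1) %/% nrs) + 1
    ok <- rr > 1 & rr < nrs & cc > 1 & cc < ncs
    cand <- cand[ok]; rr <- rr[ok]; cc <- cc[ok]
    if (length(cand) == 0) next
    v <- R[cand]
    is_max <- rep(TRUE, length(cand))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      is_max <- is_max & v >= R[cbind(rr + dr, cc + dc)]
    }
    if (i > 1) is_max <- is_max & v >= resp[[i - 1]][cand]
    if (i < length(sigmas)) is_max <- is_max & v >= resp[[i + 1]][cand]
    if (any(is_max)) {
      pts <- rbind(pts, cbind(x = cc[is_max] - 1 + x0, y = rr[is_max] - 1 + y0,
                              sigma = sigmas[i], response = v[is_max]))
    }
  }
  if (!is.null(pts)) {
    inside <- pts[, "x"] >= roi$x & pts[, "x"] <= roi$x + roi$width &
      pts[, "y"] >= roi$y & pts[, "y"] <= roi$y + roi$height
    pts <- pts[inside, , drop = FALSE]
  }
  if (is.null(pts) || nrow(pts) < 3L) {
    stop("insufficient texture: fewer than 3 interest points in ROI", call. = FALSE)
  }
  pts <- pts[order(-pts[, "response"]), , drop = FALSE]
  if (nrow(pts) > params$max_points) pts <- pts[seq_len(params$max_points), , drop = FALSE]
  pts
}
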