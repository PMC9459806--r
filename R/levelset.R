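# Aponeurosis delineation: two-phase Chan-Vese level-set segmentation
# optimised with Barzilai-Borwein gradient descent, followed by isolation of
# the fascicle-band-facing boundary and a straight-line fit.
#
# Energy (interior = {phi > 0}, c1/c2 the interior/exterior means):
#   E(phi) = rho * Length(contour)
#          + beta1 * sum_inside (I - c1)^2
#          + beta2 * sum_outside (I - c2)^2
#          + gamma * Area(inside)
# Length/area are measured with a smoothed Heaviside of width `eps` px.

#' Parameters of the Chan-Vese / Barzilai-Borwein segmentation
#'
#' Defaults follow the tracking method's published configuration: curve-length
#' weight `rho = 9e-4`, data-fidelity weights `beta1 = beta2 = 1`, area weight
#' `gamma = 0`, step size `dt = 0.51`, stopping threshold
#' `zeta = 0.18^2 * dt`, and at most 5000 iterations.
#'
#' @param rho Curve-length weight.
#' @param beta1,beta2 Inside/outside data-fidelity weights.
#' @param gamma Area weight.
#' @param dt Seed step size for the Barzilai-Borwein scheme.
#' @param zeta Stopping threshold on the mean absolute per-pixel change of
#'   the level set between iterations; defaults to `0.18^2 * dt`.
#' @param max_iter Iteration cap.
#' @param eps Width (px) of the smoothed Heaviside/Dirac.
#' @return List of class `mcv_params`.
#' @export
mcv_params <- function(rho = 9e-4, beta1 = 1, beta2 = 1, gamma = 0,
                       dt = 0.51, zeta = NULL, max_iter = 5000L, eps = 1.5) {
  if (is.null(zeta)) zeta <- 0.18^2 * dt
  stopifnot(rho >= 0, dt > 0, zeta > 0, max_iter >= 1, eps > 0)
  structure(list(rho = rho, beta1 = beta1, beta2 = beta2, gamma = gamma,
                 dt = dt, zeta = zeta, max_iter = as.integer(max_iter),
                 eps = eps),
            class = "mcv_params")
}

heaviside_eps <- function(phi, eps) 0.5 * (1 + (2 / pi) * atan(phi / eps))
dirac_eps <- function(phi, eps) (eps / pi) / (eps^2 + phi^2)

# Signed distance of every pixel to the boundary of a (convex or not)
# quadrilateral, positive inside. `box` is a 4x2 matrix of (x, y) vertices.
signed_distance_to_polygon <- function(shape, box) {
  nr <- shape[1]; nc <- shape[2]
  px <- rep(0:(nc - 1), each = nr)
  py <- rep(0:(nr - 1), times = nc)
  n <- nrow(box)
  dmin <- rep(Inf, nr * nc)
  crossings <- rep(0L, nr * nc)
  for (i in seq_len(n)) {
    a <- box[i, ]
    b <- box[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0), 1) else 0
    dx <- px - (a[1] + t * ab[1])
    dy <- py - (a[2] + t * ab[2])
    dmin <- pmin(dmin, dx * dx + dy * dy)
    # even-odd rule ray casting (ray towards +x)
    cond <- (a[2] > py) != (b[2] > py)
    if (any(cond)) {
      xint <- a[1] + (py[cond] - a[2]) / (b[2] - a[2]) * ab[1]
      hit <- px[cond] < xint
      idx <- which(cond)[hit]
      crossings[idx] <- crossings[idx] + 1L
    }
  }
  s <- ifelse(crossings %% 2L == 1L, 1, -1)
  matrix(s * sqrt(dmin), nr, nc)
}

#' Initialize a level set from a box-shaped contour
#'
#' The level set is the signed distance to the box boundary, positive inside,
#' matching the method's use of the user-drawn aponeurosis boxes as initial
#' contours.
#'
#' @param frame A [us_frame] (or plain matrix) providing the image shape.
#' @param box 4x2 matrix of quadrilateral vertices `(x, y)` in pixel
#'   coordinates (any consistent winding).
#' @return Numeric matrix `phi`, same shape as the frame.
#' @export
init_level_set <- function(frame, box) {
  px <- if (inherits(frame, "us_frame")) frame$pixels else as.matrix(frame)
  box <- as.matrix(box)
  if (nrow(box) < 3L) stop("box must have at least 3 vertices", call. = FALSE)
  nr <- nrow(px); nc <- ncol(px)
  if (all(box[, 1] < 0) || all(box[, 1] > nc - 1) ||
      all(box[, 2] < 0) || all(box[, 2] > nr - 1)) {
    stop("box entirely outside frame", call. = FALSE)
  }
  phi <- signed_distance_to_polygon(c(nr, nc), box)
  if (!any(phi > 0)) stop("box has empty interior on the pixel grid", call. = FALSE)
  phi
}

# Mean curvature div(grad phi / |grad phi|), central differences.
curvature_of <- function(phi) {
  g <- image_gradient(phi)
  nrm <- sqrt(g$gx^2 + g$gy^2 + 1e-8)
  nx <- g$gx / nrm
  ny <- g$gy / nrm
  image_gradient(nx)$gx + image_gradient(ny)$gy
}

# Energy of the relaxed two-phase model: u in [0, 1] is the soft interior
# indicator; the curve length is measured as total variation of u.
cv_energy_u <- function(img, u, p) {
  g <- image_gradient(u)
  a_in <- sum(u)
  a_out <- sum(1 - u)
  c1 <- if (a_in > 0) sum(img * u) / a_in else 0
  c2 <- if (a_out > 0) sum(img * (1 - u)) / a_out else 0
  p$rho * sum(sqrt(g$gx^2 + g$gy^2)) +
    p$beta1 * sum((img - c1)^2 * u) +
    p$beta2 * sum((img - c2)^2 * (1 - u)) +
    p$gamma * a_in
}

#' Evolve a Chan-Vese level set with Barzilai-Borwein steps
#'
#' Iterates the two-phase piecewise-constant energy with region means
#' recomputed each iteration, using the efficient unconstrained formulation:
#' the level set is relaxed to a soft interior indicator `u` in `[0, 1]`
#' (no signed-distance maintenance during evolution), the curve-length term
#' acts through the total variation of `u`, and each step is a projected
#' gradient step with a Barzilai-Borwein secant step length seeded by `dt`
#' and clipped to `[0.01 dt, 100 dt]` (the scheme is non-monotone; the clip
#' keeps the evolution finite). Stops when the mean absolute per-pixel
#' change between iterations falls below `zeta`, or at `max_iter`.
#' Intensities are normalised to `[0, 1]` internally, so the result is
#' invariant to affine rescaling of the input image.
#'
#' @param frame A [us_frame] or plain intensity matrix.
#' @param phi Initial level set, e.g. from [init_level_set()]; the interior
#'   is `{phi > 0}` on input and output.
#' @param params [mcv_params()].
#' @return List with elements `phi` (final level set, interior `> 0`),
#'   `iterations`, and `energy_trace` (energy at initialization and after
#'   each iteration).
#' @export
evolve_mcv <- function(frame, phi, params = mcv_params()) {
  img <- if (inherits(frame, "us_frame")) frame$pixels else as.matrix(frame)
  stopifnot(identical(dim(img), dim(phi)))
  p <- params
  # normalise intensities to [0, 1]: makes the evolution (and the stated
  # default weights) exactly invariant to affine intensity rescaling
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  u <- heaviside_eps(phi, p$eps)
  grad_of <- function(u) {
    a_in <- sum(u); a_out <- sum(1 - u)
    c1 <- if (a_in > 0) sum(img * u) / a_in else mean(img)
    c2 <- if (a_out > 0) sum(img * (1 - u)) / a_out else mean(img)
    -p$rho * curvature_of(u) +
      p$beta1 * (img - c1)^2 - p$beta2 * (img - c2)^2 + p$gamma
  }
  energy0 <- cv_energy_u(img, u, p)
  if (!is.finite(energy0)) stop("non-finite Chan-Vese energy at initialization", call. = FALSE)
  trace <- numeric(p$max_iter + 1L)
  trace[1] <- energy0
  g_prev <- NULL
  u_prev <- NULL
  tau <- p$dt
  it <- 0L
  while (it < p$max_iter) {
    it <- it + 1L
    g <- grad_of(u)
    if (!is.null(g_prev)) {
      svec <- u - u_prev
      yvec <- g - g_prev
      denom <- sum(svec * yvec)
      tau <- if (is.finite(denom) && abs(denom) > 1e-12) sum(svec * svec) / denom else p$dt
      if (!is.finite(tau) || tau <= 0) tau <- p$dt
      tau <- min(max(tau, 0.01 * p$dt), 100 * p$dt)
    }
    u_prev <- u
    g_prev <- g
    u <- pmin(pmax(u - tau * g, 0), 1)
    e <- cv_energy_u(img, u, p)
    if (!is.finite(e)) stop("non-finite Chan-Vese energy during evolution", call. = FALSE)
    trace[it + 1L] <- e
    if (mean(abs(u - u_prev)) < p$zeta) break
  }
  list(phi = u - 0.5, iterations = it, energy_trace = trace[seq_len(it + 1L)])
}

#' Segment an aponeurosis inside/around an initialization box
#'
#' Crops a window around `box` (the box dilated by `margin` times its
#' thickness, so that only the one aponeurosis band is in view), runs
#' [evolve_mcv()] from the box-shaped contour, and returns the binary
#' interior mask embedded in the full frame.
#'
#' @param frame A [us_frame] or matrix.
#' @param box 4x2 quadrilateral (x, y).
#' @param params [mcv_params()].
#' @param margin Window dilation as a fraction of the box height.
#' @return List: `mask` (logical full-frame matrix), `iterations`,
#'   `energy_trace`, `window` (0-based `c(x0, y0, x1, y1)` of the crop).
#' @export
segment_aponeurosis <- function(frame, box, params = mcv_params(), margin = 0.6) {
  img <- if (inherits(frame, "us_frame")) frame$pixels else as.matrix(frame)
  nr <- nrow(img); nc <- ncol(img)
  bx <- range(box[, 1]); by <- range(box[, 2])
  mg_y <- max(3, margin * (by[2] - by[1]))
  mg_x <- max(3, 0.05 * (bx[2] - bx[1]))
  x0 <- max(0, floor(bx[1] - mg_x)); x1 <- min(nc - 1, ceiling(bx[2] + mg_x))
  y0 <- max(0, floor(by[1] - mg_y)); y1 <- min(nr - 1, ceiling(by[2] + mg_y))
  if (x1 - x0 < 2 || y1 - y0 < 2) stop("box window degenerate after clipping", call. = FALSE)
  sub <- img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  box_local <- cbind(box[, 1] - x0, box[, 2] - y0)
  phi0 <- init_level_set(sub, box_local)
  ev <- evolve_mcv(sub, phi0, params)
  mask <- matrix(FALSE, nr, nc)
  inner <- ev$phi > 0
  mask[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- inner
  c1 <- if (any(inner)) mean(sub[inner]) else NA_real_
  c2 <- if (!all(inner)) mean(sub[!inner]) else NA_real_
  list(mask = mask, iterations = ev$iterations, energy_trace = ev$energy_trace,
       window = c(x0, y0, x1, y1), c1 = c1, c2 = c2)
}

# Subpixel refinement of per-column boundary pixels: locate the intensity
# crossing of the region-mean threshold tau = (c1 + c2) / 2 within a few
# rows of the integer mask boundary and interpolate linearly. Stabilises the
# line fit against the +/- 1 px quantisation of the binary mask (the fitted
# columns are averaged by OLS, so per-column noise washes out).
refine_boundary_subpixel <- function(img, pts, side, tau, reach = 3L) {
  nr <- nrow(img)
  y <- pts[, 2]
  x <- pts[, 1]
  step <- if (side == "deep") -1L else 1L  # direction away from the band
  y_ref <- as.numeric(y)
  found <- rep(FALSE, length(y))
  at <- function(r) img[cbind(pmin(pmax(r, 0), nr - 1) + 1, x + 1)]
  for (o in 0:reach) {
    r_in <- y + step * o        # candidate in-band row
    r_out <- r_in + step        # its off-band neighbour
    ok <- !found & r_out >= 0 & r_out <= nr - 1 & r_in >= 0 & r_in <= nr - 1
    ii <- at(r_in); io <- at(r_out)
    hit <- ok & io < tau & ii >= tau & (ii - io) > 1e-6
    frac <- (ii - tau) / (ii - io)
    y_ref[hit] <- r_in[hit] + step * pmin(pmax(frac[hit], 0), 1)
    found <- found | hit
  }
  cbind(x = x, y = y_ref)
}

#' Extract the fascicle-band-facing boundary of a segmented aponeurosis
#'
#' Keeps the largest connected component of the mask, then returns one
#' boundary pixel per column: for the superficial aponeurosis the bottom-most
#' (maximal y) pixel, for the deep aponeurosis the top-most (minimal y) pixel
#' -- i.e. the edge facing the fascicle band.
#'
#' @param mask Logical matrix.
#' @param side `"superficial"` or `"deep"`.
#' @return Matrix with columns `x`, `y` (0-based), ordered by `x`.
#' @export
extract_band_boundary <- function(mask, side = c("superficial", "deep")) {
  side <- match.arg(side)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  # EBImage works on (x, y)-indexed images; transpose our [row, col] matrix
  lab <- EBImage::bwlabel(t(mask * 1))
  labv <- as.integer(lab)
  tab <- tabulate(labv[labv > 0])
  keep <- which.max(tab)
  comp <- t(matrix(labv == keep, nrow(lab), ncol(lab)))
  cols <- which(colSums(comp) > 0)
  if (length(cols) < 2L) stop("fewer than 2 columns with mask pixels", call. = FALSE)
  ys <- vapply(cols, function(j) {
    rows <- which(comp[, j])
    if (side == "superficial") max(rows) else min(rows)
  }, numeric(1))
  cbind(x = cols - 1, y = ys - 1)
}

#' Fit a straight line to boundary pixels
#'
#' Ordinary least squares of y on x. Near-vertical fits (|slope| beyond
#' tan 80 degrees) are rejected, as are single-column inputs.
#'
#' @param pixels Matrix with columns `x`, `y` (0-based pixel coordinates).
#' @return An object of class `boundary_line`: list with `slope`,
#'   `intercept`, `x_extent`, `n_support`.
#' @export
fit_boundary_line <- function(pixels) {
  pixels <- as.matrix(pixels)
  x <- pixels[, 1]; y <- pixels[, 2]
  if (length(unique(x)) < 2L) stop("degenerate fit: all pixels share one x", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  if (abs(slope) >= tan(80 * pi / 180)) {
    stop("near-vertical boundary fit rejected", call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept,
         x_extent = range(x), n_support = length(x)),
    class = "boundary_line"
  )
}

#' @export
print.boundary_line <- function(x, ...) {
  cat(sprintf("<boundary_line: y = %.4g x + %.4g, x in [%g, %g], n = %d>\n",
              x$slope, x$intercept, x$x_extent[1], x$x_extent[2], x$n_support))
  invisible(x)
}

# Convenience: segment + boundary + subpixel refinement + fit in one step.
delineate_boundary <- function(frame, box, side, params = mcv_params(),
                               refine = TRUE) {
  img <- if (inherits(frame, "us_frame")) frame$pixels else as.matrix(frame)
  seg <- segment_aponeurosis(img, box, params)
  px <- extract_band_boundary(seg$mask, side)
  if (refine && is.finite(seg$c1) && is.finite(seg$c2)) {
    px <- refine_boundary_subpixel(img, px, side, (seg$c1 + seg$c2) / 2)
  }
  list(line = fit_boundary_line(px), mask = seg$mask, iterations = seg$iterations)
}
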