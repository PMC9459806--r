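# Synthetic phantom videos of pennate muscle: two bright quasi-horizontal
# aponeurosis bands enclosing a darker fascicle band filled with oblique,
# dashed, nonuniformly spaced striations; multiplicative speckle noise; and a
# known per-frame global affine motion with analytic fascicle length /
# pennation angle ground truth.

# Evaluate expr with a locally-seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Line through two points -> c(slope, intercept); near-vertical is an error.
line_through <- function(p, q) {
  dx <- q[1] - p[1]
  if (abs(dx) < 1e-9) stop("vertical line in phantom geometry", call. = FALSE)
  m <- (q[2] - p[2]) / dx
  c(m, p[2] - m * p[1])
}

apply_affine <- function(M, pts) {
  pts <- matrix(pts, ncol = 2)
  cbind(M[1, 1] * pts[, 1] + M[1, 2] * pts[, 2] + M[1, 3],
        M[2, 1] * pts[, 1] + M[2, 2] * pts[, 2] + M[2, 3])
}

transform_line <- function(mb, M) {
  p <- apply_affine(M, c(0, mb[2]))
  q <- apply_affine(M, c(1000, mb[1] * 1000 + mb[2]))
  line_through(p, q)
}

#' Specify a synthetic pennate-muscle phantom video
#'
#' The phantom emulates the B-mode appearance of pennate muscle: a
#' superficial and a deep aponeurosis as bright bands, a darker fascicle band
#' between them textured with oblique dashed striations (nonuniform spacing
#' and brightness so that interest-point detectors find 2-D structure), and
#' multiplicative speckle. The superficial band position is derived from
#' `fl0` and `pa0` so that `fl0 * sin(pa0)` equals the band gap times the
#' calibration.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param mm_per_pixel Isotropic calibration (mm/px).
#' @param pa0 Initial pennation angle, degrees, in (5, 60).
#' @param fl0 Initial fascicle length, mm.
#' @param deep_y Row (0-based y) of the deep aponeurosis' upper edge (the
#'   bottom boundary of the fascicle band) at the image centre.
#' @param band_slope Slope of both aponeuroses (dimensionless dy/dx).
#' @param band_thickness Aponeurosis band thickness in px.
#' @param band_intensity,background,striation_intensity Intensities in
#'   `[0, 1]`.
#' @param striation_spacing Mean striation spacing along the band normal, px.
#' @param speckle_sigma Multiplicative speckle scale (0 = noiseless).
#' @param motion One of `list(type = "static")`,
#'   `list(type = "translate", delta = c(dx, dy))` (whole scene, px/frame),
#'   `list(type = "contraction", pa1 =, fl1 =)` (linear schedules, deep
#'   aponeurosis fixed), or `list(type = "affine", matrices = <list of 2x3>)`
#'   mapping frame-0 coordinates to each frame.
#' @param n_frames Number of frames.
#' @param seed Integer seed controlling striation layout and speckle.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(224L, 320L), mm_per_pixel = 0.2,
                         pa0 = 20, fl0 = 50, deep_y = 170, band_slope = 0,
                         band_thickness = 14, band_intensity = 0.85,
                         background = 0.12, striation_intensity = 0.42,
                         striation_spacing = 9, speckle_sigma = 0,
                         motion = list(type = "static"), n_frames = 10L,
                         seed = 1L) {
  stopifnot(pa0 > 5, pa0 < 60, fl0 > 0, mm_per_pixel > 0, n_frames >= 1)
  nr <- image_shape[1]; nc <- image_shape[2]
  gap_px <- fl0 * sin(pa0 * pi / 180) / mm_per_pixel  # perpendicular gap
  gap_v <- gap_px / cos(atan(band_slope))             # vertical offset
  cx <- (nc - 1) / 2
  deep_inner <- c(band_slope, deep_y - band_slope * cx)
  sup_inner <- c(band_slope, deep_y - gap_v - band_slope * cx)
  # bands must be disjoint and inside the image with headroom for motion
  if (gap_px < 2 * band_thickness) stop("bands overlap: gap too small", call. = FALSE)
  edge_y <- c(sup_inner[2], sup_inner[2] + band_slope * (nc - 1)) - band_thickness
  if (any(edge_y < 2)) stop("superficial band leaves image bounds", call. = FALSE)
  if (deep_y + band_thickness > nr - 3) stop("deep band leaves image bounds", call. = FALSE)
  if (!motion$type %in% c("static", "translate", "contraction", "affine")) {
    stop("unknown motion type", call. = FALSE)
  }
  if (motion$type == "contraction" && band_slope != 0) {
    stop("contraction motion requires horizontal bands", call. = FALSE)
  }
  spec <- structure(
    list(image_shape = as.integer(image_shape), mm_per_pixel = mm_per_pixel,
         pa0 = pa0, fl0 = fl0, gap_px = gap_px,
         deep_inner = deep_inner, sup_inner = sup_inner,
         band_slope = band_slope, band_thickness = band_thickness,
         band_intensity = band_intensity, background = background,
         striation_intensity = striation_intensity,
         striation_spacing = striation_spacing,
         speckle_sigma = speckle_sigma, motion = motion,
         n_frames = as.integer(n_frames), seed = as.integer(seed)),
    class = "phantom_spec"
  )
  spec$fascicle_dir <- phantom_fascicle_dir(spec)
  spec$striations <- with_local_seed(spec$seed, make_striations(spec))
  # tissue-locked speckle: one multiplicative field in frame-0 coordinates,
  # warped with the motion (ultrasound speckle is scatterer-generated and
  # moves with the tissue; per-frame independent noise would model
  # electronic noise instead)
  if (speckle_sigma > 0) {
    spec$speckle_field <- with_local_seed(spec$seed * 7919L,
                                          matrix(rnorm(nr * nc), nr, nc))
  }
  # fail early if the scheduled motion pushes geometry out of bounds
  gt <- ground_truth(spec)
  ins <- attr(gt, "insertions")
  if (any(ins[, c("ax", "bx")] < 0) || any(ins[, c("ax", "bx")] > nc - 1) ||
      any(ins[, c("ay", "by")] < 0) || any(ins[, c("ay", "by")] > nr - 1)) {
    stop("motion schedule moves insertion points outside the image", call. = FALSE)
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec: %d frames %dx%d px, %.3g mm/px, FL0 %.3g mm, PA0 %.3g deg, speckle %.3g, motion '%s'>\n",
    x$n_frames, x$image_shape[1], x$image_shape[2], x$mm_per_pixel,
    x$fl0, x$pa0, x$speckle_sigma, x$motion$type
  ))
  invisible(x)
}

# Unit direction of the fascicles at frame 0 (pointing up-and-right, i.e.
# from the deep towards the superficial aponeurosis).
phantom_fascicle_dir <- function(spec) {
  ang <- atan(spec$band_slope) - spec$pa0 * pi / 180
  c(cos(ang), sin(ang))
}

# Frame-0 insertion points of the central fascicle line.
phantom_insertions0 <- function(spec) {
  nc <- spec$image_shape[2]
  cx <- (nc - 1) / 2
  mid_y <- (spec$sup_inner[1] * cx + spec$sup_inner[2] +
              spec$deep_inner[1] * cx + spec$deep_inner[2]) / 2
  m0 <- c(cx, mid_y)
  u <- spec$fascicle_dir
  seg <- rbind(m0 - 10 * u, m0 + 10 * u)
  A <- intersect_line_boundary(seg, list(slope = spec$sup_inner[1], intercept = spec$sup_inner[2]))
  B <- intersect_line_boundary(seg, list(slope = spec$deep_inner[1], intercept = spec$deep_inner[2]))
  list(A = unname(A), B = unname(B), mid = m0, u = u)
}

# Per-frame 2x3 affine matrices mapping frame-0 coordinates to frame t.
phantom_affines <- function(spec) {
  n <- spec$n_frames
  out <- vector("list", n)
  idm <- cbind(diag(2), c(0, 0))
  switch(spec$motion$type,
    static = for (t in seq_len(n)) out[[t]] <- idm,
    translate = {
      d <- spec$motion$delta
      for (t in seq_len(n)) out[[t]] <- cbind(diag(2), (t - 1) * d)
    },
    affine = {
      stopifnot(length(spec$motion$matrices) == n)
      out <- spec$motion$matrices
    },
    contraction = {
      ins <- phantom_insertions0(spec)
      yd <- spec$deep_inner[2]
      g0 <- spec$gap_px
      fr <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
      pa_t <- spec$pa0 + fr * (spec$motion$pa1 - spec$pa0)
      fl_t <- spec$fl0 + fr * (spec$motion$fl1 - spec$fl0)
      for (t in seq_len(n)) {
        g_t <- fl_t[t] * sin(pa_t[t] * pi / 180) / spec$mm_per_pixel
        l_t <- fl_t[t] / spec$mm_per_pixel
        a_t <- c(ins$B[1] + l_t * cos(pa_t[t] * pi / 180), yd - g_t)
        k_t <- (a_t[1] - ins$A[1]) / g0
        sy <- g_t / g0
        out[[t]] <- rbind(c(1, -k_t, k_t * yd), c(0, sy, yd * (1 - sy)))
      }
    }
  )
  out
}

#' Analytic ground truth of a phantom video
#'
#' Per-frame fascicle length and pennation angle computed by mapping the
#' frame-0 fascicle segment and aponeurosis boundary lines through the
#' scheduled affine motion (affine maps preserve incidence, so insertion
#' points transform directly).
#'
#' @param spec A [phantom_spec()].
#' @return Tibble with columns `frame`, `fl_mm`, `pa_deg`; the per-frame 2x3
#'   affines are attached as attribute `"affines"` and the insertion points
#'   as attribute `"insertions"`.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  aff <- phantom_affines(spec)
  ins0 <- phantom_insertions0(spec)
  n <- spec$n_frames
  fl <- pa <- numeric(n)
  insm <- matrix(0, n, 4, dimnames = list(NULL, c("ax", "ay", "bx", "by")))
  for (t in seq_len(n)) {
    M <- aff[[t]]
    A <- as.numeric(apply_affine(M, ins0$A))
    B <- as.numeric(apply_affine(M, ins0$B))
    deep_t <- transform_line(spec$deep_inner, M)
    fl[t] <- compute_fl(A, B, spec$mm_per_pixel)
    pa[t] <- compute_pa(rbind(A, B), list(slope = deep_t[1], intercept = deep_t[2]))
    insm[t, ] <- c(A, B)
  }
  out <- tibble::tibble(frame = seq_len(n) - 1L, fl_mm = fl, pa_deg = pa)
  attr(out, "affines") <- aff
  attr(out, "insertions") <- insm
  out
}

# Dashed striation segments in frame-0 coordinates: list of matrices
# rbind(p, q) plus per-dash intensity factors.
make_striations <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  u <- spec$fascicle_dir
  nrm <- c(-u[2], u[1])          # unit normal
  ins <- phantom_insertions0(spec)
  m0 <- ins$mid
  # offsets covering the band's corner points, projected on the normal
  corners <- rbind(
    c(0, spec$sup_inner[2]), c(nc - 1, spec$sup_inner[1] * (nc - 1) + spec$sup_inner[2]),
    c(0, spec$deep_inner[2]), c(nc - 1, spec$deep_inner[1] * (nc - 1) + spec$deep_inner[2])
  )
  proj <- (corners[, 1] - m0[1]) * nrm[1] + (corners[, 2] - m0[2]) * nrm[2]
  segs <- list()
  ints <- numeric(0)
  off <- min(proj) - 2
  ymarg <- 2.5
  while (off < max(proj) + 2) {
    p0 <- m0 + off * nrm
    # param range t where the line p0 + t*u stays inside the band (with a
    # vertical margin) and inside the image: each edge gives a half-space
    # constraint c0 + t*den >= 0
    tt <- c(-2 * (nr + nc), 2 * (nr + nc))
    cons <- list(
      # below the superficial inner edge: y - (m x + b + ymarg) >= 0
      c(1, spec$sup_inner[1], spec$sup_inner[2] + ymarg),
      # above the deep inner edge: (m x + b - ymarg) - y >= 0
      c(-1, spec$deep_inner[1], spec$deep_inner[2] - ymarg)
    )
    for (cn in cons) {
      c0 <- cn[1] * (p0[2] - cn[2] * p0[1] - cn[3])
      den <- cn[1] * (u[2] - cn[2] * u[1])
      if (abs(den) < 1e-12) {
        if (c0 < 0) tt <- c(1, 0)
        next
      }
      tc <- -c0 / den
      if (den > 0) tt[1] <- max(tt[1], tc) else tt[2] <- min(tt[2], tc)
    }
    if (abs(u[1]) > 1e-9) {
      tx <- sort(c((2 - p0[1]) / u[1], (nc - 3 - p0[1]) / u[1]))
      tt <- c(max(tt[1], tx[1]), min(tt[2], tx[2]))
    }
    if (tt[2] - tt[1] > 6) {
      t <- tt[1] + runif(1, 0, 12)
      while (t < tt[2] - 4) {
        dash <- runif(1, 14, 42)
        t2 <- min(t + dash, tt[2])
        if (runif(1) > 0.12) {        # occasionally drop a dash entirely
          lat <- runif(1, -0.8, 0.8)  # small lateral wobble per dash
          p <- p0 + t * u + lat * nrm
          q <- p0 + t2 * u + lat * nrm
          segs[[length(segs) + 1L]] <- rbind(p, q)
          ints <- c(ints, runif(1, 0.55, 1.3))
        }
        t <- t2 + runif(1, 5, 16)
      }
    }
    off <- off + spec$striation_spacing * (0.45 + 0.55 * stats::rexp(1))
  }
  list(segments = segs, intensities = ints)
}

# Anti-aliased coverage of the region between two non-vertical lines
# (top edge, bottom edge), as a full-frame matrix in [0, 1].
band_coverage <- function(shape, top, bottom) {
  nr <- shape[1]; nc <- shape[2]
  xs <- 0:(nc - 1)
  yT <- matrix(top[1] * xs + top[2], nr, nc, byrow = TRUE)
  yB <- matrix(bottom[1] * xs + bottom[2], nr, nc, byrow = TRUE)
  Y <- matrix(0:(nr - 1), nr, nc)
  pmin(pmax(pmin(Y - yT, yB - Y) + 0.5, 0), 1)
}

draw_segment <- function(img, p, q, amp, width = 1.1) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(0, floor(min(p[1], q[1]) - width - 1))
  x1 <- min(nc - 1, ceiling(max(p[1], q[1]) + width + 1))
  y0 <- max(0, floor(min(p[2], q[2]) - width - 1))
  y1 <- min(nr - 1, ceiling(max(p[2], q[2]) + width + 1))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  d <- q - p
  len2 <- sum(d^2)
  t <- if (len2 > 0) pmin(pmax(((px - p[1]) * d[1] + (py - p[2]) * d[2]) / len2, 0), 1) else 0
  dist <- sqrt((px - (p[1] + t * d[1]))^2 + (py - (p[2] + t * d[2]))^2)
  contrib <- amp * pmax(0, 1 - dist / width)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + matrix(contrib, length(ys), length(xs))
  img
}

#' Render one phantom frame
#'
#' Draws both aponeurosis bands and the striations at the frame-`t` geometry,
#' then applies multiplicative speckle `I * (1 + sigma * eta)`, clipping to
#' `[0, 1]`. `eta` is a standard-normal field defined once in frame-0
#' coordinates and warped with the scheduled motion, so the speckle pattern
#' moves with the tissue as it does in B-mode imaging. Deterministic for a
#' given spec.
#'
#' @param spec A [phantom_spec()].
#' @param t Frame index, 0-based, `0 <= t < n_frames`.
#' @return A [us_frame].
#' @export
render_frame <- function(spec, t) {
  stopifnot(inherits(spec, "phantom_spec"), t >= 0, t < spec$n_frames)
  M <- phantom_affines(spec)[[t + 1]]
  shape <- spec$image_shape
  th <- spec$band_thickness
  sup_outer <- c(spec$sup_inner[1], spec$sup_inner[2] - th)
  deep_outer <- c(spec$deep_inner[1], spec$deep_inner[2] + th)
  cov_sup <- band_coverage(shape, transform_line(sup_outer, M), transform_line(spec$sup_inner, M))
  cov_deep <- band_coverage(shape, transform_line(spec$deep_inner, M), transform_line(deep_outer, M))
  img <- matrix(spec$background, shape[1], shape[2])
  img <- img + (spec$band_intensity - spec$background) * pmax(cov_sup, cov_deep)
  for (i in seq_along(spec$striations$segments)) {
    s <- apply_affine(M, spec$striations$segments[[i]])
    img <- draw_segment(img, s[1, ], s[2, ],
                        spec$striation_intensity * spec$striations$intensities[i])
  }
  img <- pmin(img, 1)
  if (spec$speckle_sigma > 0) {
    nr <- nrow(img); nc <- ncol(img)
    if (t == 0) {
      eta <- spec$speckle_field
    } else {
      Minv <- solve(rbind(M, c(0, 0, 1)))[1:2, ]
      px <- rep(0:(nc - 1), each = nr)
      py <- rep(0:(nr - 1), times = nc)
      src <- apply_affine(Minv, cbind(px, py))
      eta <- matrix(bilinear_sample(spec$speckle_field, src[, 1], src[, 2]), nr, nc)
    }
    img <- img * (1 + spec$speckle_sigma * eta)
  }
  us_frame(pmin(pmax(img, 0), 1), index = t, mm_per_pixel = spec$mm_per_pixel)
}

#' Render the full phantom video
#'
#' @param spec A [phantom_spec()].
#' @return A [us_video].
#' @export
phantom_video <- function(spec) {
  us_video(lapply(seq_len(spec$n_frames) - 1L, function(t) render_frame(spec, t)))
}

#' Ground-truth aponeurosis band mask of a phantom frame
#'
#' @param spec A [phantom_spec()].
#' @param t Frame index (0-based).
#' @param side `"superficial"` or `"deep"`.
#' @return Logical full-frame matrix.
#' @export
phantom_band_mask <- function(spec, t, side = c("superficial", "deep")) {
  side <- match.arg(side)
  M <- phantom_affines(spec)[[t + 1]]
  th <- spec$band_thickness
  if (side == "superficial") {
    top <- c(spec$sup_inner[1], spec$sup_inner[2] - th)
    bot <- spec$sup_inner
  } else {
    top <- spec$deep_inner
    bot <- c(spec$deep_inner[1], spec$deep_inner[2] + th)
  }
  # boundary-inclusive: pixels whose centres lie on the band edge count
  band_coverage(spec$image_shape, transform_line(top, M), transform_line(bot, M)) >= 0.5
}

#' Build an initialization record for a phantom (the simulated user input)
#'
#' Places the aponeurosis lines on the true band boundaries with a box
#' thickness that encloses the full band (emulating the >= 90% enclosure the
#' manual protocol aims for), and the fascicle direction line through the
#' image centre, parallel to the true striation direction. Optional
#' perturbations reproduce the initialization-sensitivity scenarios: a
#' parallel shift of EF along the deep boundary, a rotation obtained by
#' moving E and F in opposite directions along the line normal, and a box
#' thickness change.
#'
#' @param spec A [phantom_spec()].
#' @param shift_px Signed parallel shift of EF along the deep-boundary
#'   direction (px).
#' @param rotate_px Signed displacement `d`: E moves by `+d` and F by `-d`
#'   along the normal to EF (px).
#' @param thickness_delta Added to both box thicknesses (px).
#' @return An [init_record].
#' @export
make_init <- function(spec, shift_px = 0, rotate_px = 0, thickness_delta = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  xm <- 4
  xs <- c(xm, nc - 1 - xm)
  line_pts <- function(mb) rbind(c(xs[1], mb[1] * xs[1] + mb[2]),
                                 c(xs[2], mb[1] * xs[2] + mb[2]))
  th <- spec$band_thickness + 4 + thickness_delta
  ins <- phantom_insertions0(spec)
  u <- ins$u
  half <- 0.45 * spec$fl0 / spec$mm_per_pixel
  E <- ins$mid - half * u
  F <- ins$mid + half * u
  if (shift_px != 0) {
    dd <- c(1, spec$deep_inner[1])
    dd <- dd / sqrt(sum(dd^2))
    E <- E + shift_px * dd
    F <- F + shift_px * dd
  }
  if (rotate_px != 0) {
    nrml <- c(-u[2], u[1])
    E <- E + rotate_px * nrml
    F <- F - rotate_px * nrml
  }
  init_record(
    deep_line = line_pts(spec$deep_inner),
    deep_thickness = th,
    superficial_line = line_pts(spec$sup_inner),
    superficial_thickness = th,
    fascicle_line = rbind(E, F),
    frame_shape = c(nr, nc)
  )
}
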