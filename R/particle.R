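# Particle-filter tracking of the aponeurosis boxes. The state is a
# 6-parameter affine warp [x, y, theta, s, a, psi] mapping a canonical
# template grid to image coordinates; the transition is independent Gaussian
# diffusion on each parameter; the observation likelihood comes from the
# approximation error of the warped patch under a sparse representation over
# target templates plus positive/negative single-pixel (trivial) templates,
# solved with accelerated proximal gradient (FISTA) steps.

#' Particle-filter and sparse-representation parameters
#'
#' Defaults are the published configuration: 800 particles, 10 target
#' templates of 39 x 39 px, L1 weights 0.2 (target) and 0.001 (trivial),
#' Lipschitz constant 8, 5 proximal-gradient iterations, occlusion weighting
#' 10. The published transition variances `[0.03, 0.0005, 0.0005, 0.03, 1, 1]`
#' follow the l1-tracker convention of perturbing the six affine-matrix
#' entries (diagonal, off-diagonal, translation); mapped onto the geometric
#' state this gives variances `s, a = 0.03`, `theta, psi = 5e-4`,
#' `x, y = 1`. Override `variances` (a named vector) to change the mapping.
#'
#' @param n_particles Number of particles M.
#' @param variances Named numeric vector of transition variances for
#'   `x, y, theta, s, a, psi`.
#' @param n_templates Number of target templates (frame-0 crop + jitters).
#' @param template_size `c(h, w)` of the template grid, px.
#' @param lambda_target,lambda_trivial L1 penalties for target and trivial
#'   coefficients.
#' @param occlusion_weight Multiplier on the trivial penalty when occlusion
#'   is detected.
#' @param occlusion_threshold Trivial-coefficient L1 energy, as a fraction of
#'   the patch L1 norm, that triggers the occlusion re-solve.
#' @param lipschitz Gradient step is `1 / lipschitz`.
#' @param max_apg_iter Proximal-gradient iterations per particle.
#' @param lambda_lik Likelihood sharpness: weight `exp(-lambda_lik * err)`.
#'   The default resolves sub-pixel box displacements on L2-normalised
#'   patches; smaller values flatten the posterior and make the tracker lag.
#' @param obs_blur_sigma Gaussian blur (px) applied to each frame before
#'   patch extraction; suppresses speckle and the aliasing caused by
#'   resampling a wide box onto the template grid.
#' @return List of class `pf_params`.
#' @export
pf_params <- function(n_particles = 800L,
                      variances = c(x = 1, y = 1, theta = 5e-4, s = 0.03,
                                    a = 0.03, psi = 5e-4),
                      n_templates = 10L, template_size = c(39L, 39L),
                      lambda_target = 0.2, lambda_trivial = 0.001,
                      occlusion_weight = 10, occlusion_threshold = 0.1,
                      lipschitz = 8, max_apg_iter = 5L, lambda_lik = 60,
                      obs_blur_sigma = 1.5) {
  stopifnot(n_particles >= 1, all(variances >= 0),
            all(c("x", "y", "theta", "s", "a", "psi") %in% names(variances)),
            n_templates >= 1, length(template_size) == 2, lipschitz > 0)
  structure(list(n_particles = as.integer(n_particles),
                 variances = variances[c("x", "y", "theta", "s", "a", "psi")],
                 n_templates = as.integer(n_templates),
                 template_size = as.integer(template_size),
                 lambda_target = lambda_target, lambda_trivial = lambda_trivial,
                 occlusion_weight = occlusion_weight,
                 occlusion_threshold = occlusion_threshold,
                 lipschitz = lipschitz, max_apg_iter = as.integer(max_apg_iter),
                 lambda_lik = lambda_lik, obs_blur_sigma = obs_blur_sigma),
            class = "pf_params")
}

state_names <- c("x", "y", "theta", "s", "a", "psi")

#' Affine warp matrix of a particle state
#'
#' Composes translation(x, y) . rotation(theta) . scale(s, s*a) . shear(psi)
#' into a 2x3 matrix mapping centred template coordinates to image
#' coordinates.
#'
#' @param state Numeric vector `c(x, y, theta, s, a, psi)`.
#' @param box_shape Unused by the matrix itself (the template grid carries
#'   the extent); kept for interface clarity.
#' @return 2x3 affine matrix.
#' @export
state_to_warp <- function(state, box_shape = NULL) {
  x <- state[1]; y <- state[2]; th <- state[3]
  s <- state[4]; a <- state[5]; psi <- state[6]
  cs <- cos(th); sn <- sin(th)
  # R(theta) %*% diag(s, s*a) %*% [[1, psi], [0, 1]]
  l11 <- cs * s
  l12 <- cs * s * psi - sn * s * a
  l21 <- sn * s
  l22 <- sn * s * psi + cs * s * a
  rbind(c(l11, l12, x), c(l21, l22, y))
}

# Inverse mapping: state from a parallelogram box (4x2 corners ordered
# p1 -> p2 along the aponeurosis line, p3, p4 closing the loop).
state_from_box <- function(box, template_size) {
  h <- template_size[1]; w <- template_size[2]
  ctr <- colMeans(box[1:4, ])
  u <- box[2, ] - box[1, ]
  v <- box[4, ] - box[1, ]
  th <- atan2(u[2], u[1])
  wlen <- sqrt(sum(u^2))
  s <- wlen / (w - 1)
  # component of v along u is shear, perpendicular is height
  uhat <- u / wlen
  vpar <- sum(v * uhat)                      # shear component
  vperp <- v[1] * (-uhat[2]) + v[2] * uhat[1] # height component (>0 for
  # corners ordered so that p4 lies on the +90deg side of p1->p2)
  sa <- vperp / (h - 1)
  c(x = ctr[1], y = ctr[2], theta = th, s = s, a = sa / s,
    psi = vpar / (s * (h - 1)))
}

box_from_state <- function(state, template_size) {
  h <- template_size[1]; w <- template_size[2]
  hw <- (w - 1) / 2; hh <- (h - 1) / 2
  corners <- rbind(c(-hw, -hh), c(hw, -hh), c(hw, hh), c(-hw, hh))
  M <- state_to_warp(state)
  apply_affine(M, corners)
}

# Centred template grid as two vectors of length h*w (column-major).
template_grid <- function(template_size) {
  h <- template_size[1]; w <- template_size[2]
  pu <- rep(seq(-(w - 1) / 2, (w - 1) / 2, length.out = w), each = h)
  pv <- rep(seq(-(h - 1) / 2, (h - 1) / 2, length.out = h), times = w)
  list(pu = pu, pv = pv)
}

# Sample the image patch of every particle: returns n_px x M matrix plus the
# fraction of sample points falling outside the frame.
extract_patches <- function(img, states, params) {
  g <- template_grid(params$template_size)
  M <- nrow(states)
  cs <- cos(states[, 3]); sn <- sin(states[, 3])
  s <- states[, 4]; sa <- states[, 4] * states[, 5]; psi <- states[, 6]
  l11 <- cs * s; l12 <- cs * s * psi - sn * sa
  l21 <- sn * s; l22 <- sn * s * psi + cs * sa
  qx <- outer(g$pu, l11) + outer(g$pv, l12) + rep(states[, 1], each = length(g$pu))
  qy <- outer(g$pu, l21) + outer(g$pv, l22) + rep(states[, 2], each = length(g$pu))
  nr <- nrow(img); nc <- ncol(img)
  outside <- colMeans(qx < 0 | qx > nc - 1 | qy < 0 | qy > nr - 1)
  X <- matrix(bilinear_sample(img, as.numeric(qx), as.numeric(qy)),
              nrow = length(g$pu))
  list(X = X, frac_outside = outside)
}

l2_normalize_cols <- function(X) {
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  sweep(X, 2, nrm, "/")
}

#' Build the sparse-representation template dictionary
#'
#' The first target template is the frame-0 box content resampled to the
#' template grid; the remaining templates are small spatial jitters (+/- 2 px
#' shifts) of the same crop. All templates are L2-normalised. The trivial
#' templates (one positive and one negative unit vector per pixel) are
#' implicit in the coder and never materialised.
#'
#' @param frame [us_frame] or matrix (frame 0).
#' @param box 4x2 initialization box.
#' @param params [pf_params()].
#' @return List of class `template_dictionary`: `templates` (n_px x
#'   n_templates), `state0`, `params`.
#' @export
template_dictionary <- function(frame, box, params = pf_params()) {
  img <- if (inherits(frame, "us_frame")) frame$pixels else as.matrix(frame)
  state0 <- state_from_box(box, params$template_size)
  jit <- rbind(c(0, 0), c(2, 0), c(-2, 0), c(0, 2), c(0, -2),
               c(2, 2), c(-2, -2), c(2, -2), c(-2, 2), c(1, 1))
  jit <- jit[seq_len(min(nrow(jit), params$n_templates)), , drop = FALSE]
  states <- matrix(rep(as.numeric(state0), each = nrow(jit)), nrow = nrow(jit))
  states[, 1] <- states[, 1] + jit[, 1]
  states[, 2] <- states[, 2] + jit[, 2]
  T <- extract_patches(img, states, params)$X
  structure(list(templates = l2_normalize_cols(T), state0 = state0,
                 template_size = params$template_size),
            class = "template_dictionary")
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Sparse coding of observation patches by accelerated proximal gradient
#'
#' Minimises `0.5 ||x - T a - e||^2 + lambda_target ||a||_1 +
#' lambda_trivial ||e||_1` with `a >= 0`, where `e` collects the
#' positive-minus-negative trivial (single-pixel) coefficients, by FISTA
#' iterations with step `1 / lipschitz`. Operates on a whole matrix of
#' patches at once (one column per particle).
#'
#' @param X Matrix of L2-normalised patches (n_px x m), or a single vector.
#' @param dict A [template_dictionary()].
#' @param params [pf_params()].
#' @param lambda_trivial Override of the trivial penalty (used for the
#'   occlusion re-solve).
#' @param max_iter Override of the iteration budget.
#' @return List: `coef_target` (K x m), `coef_trivial` (n_px x m),
#'   `err_target` = `||x - T a||^2`, `err_total` = `||x - T a - e||^2`,
#'   `trivial_l1` per column.
#' @export
sparse_code <- function(X, dict, params = pf_params(),
                        lambda_trivial = NULL, max_iter = NULL) {
  X <- as.matrix(X)
  Tm <- dict$templates
  if (nrow(X) != nrow(Tm)) stop("patch/template dimension mismatch", call. = FALSE)
  lt <- params$lambda_target
  le <- if (is.null(lambda_trivial)) params$lambda_trivial else lambda_trivial
  L <- params$lipschitz
  niter <- if (is.null(max_iter)) params$max_apg_iter else max_iter
  K <- ncol(Tm); m <- ncol(X)
  A <- matrix(0, K, m); E <- matrix(0, nrow(X), m)
  YA <- A; YE <- E
  tk <- 1
  for (it in seq_len(niter)) {
    R <- Tm %*% YA + YE - X
    GA <- crossprod(Tm, R)
    A_new <- pmax(YA - GA / L - lt / L, 0)
    E_new <- soft_threshold(YE - R / L, le / L)
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    mom <- (tk - 1) / tk1
    YA <- A_new + mom * (A_new - A)
    YE <- E_new + mom * (E_new - E)
    A <- A_new; E <- E_new; tk <- tk1
  }
  RT <- X - Tm %*% A
  list(coef_target = A, coef_trivial = E,
       err_target = colSums(RT^2),
       err_total = colSums((RT - E)^2),
       trivial_l1 = colSums(abs(E)))
}

#' Propagate particles through the Gaussian transition model
#'
#' Each state parameter is perturbed independently with the configured
#' variance; weights are unchanged.
#'
#' @param particles List with `states` (M x 6) and `weights` (length M).
#' @param params [pf_params()].
#' @return Particle set with perturbed states.
#' @export
pf_predict <- function(particles, params = pf_params()) {
  st <- particles$states
  M <- nrow(st)
  sds <- sqrt(params$variances)
  # translation, rotation and skew are additive; the scale-like parameters
  # s and a are perturbed multiplicatively (the published variances follow
  # the affine-matrix-entry convention, where the diagonal entries carry
  # the scales, so their noise is relative)
  for (j in c(1L, 2L, 3L, 6L)) {
    if (sds[j] > 0) st[, j] <- st[, j] + rnorm(M, 0, sds[j])
  }
  for (j in c(4L, 5L)) {
    if (sds[j] > 0) st[, j] <- st[, j] * (1 + rnorm(M, 0, sds[j]))
  }
  list(states = st, weights = particles$weights)
}

#' Weight particles by the sparse-representation observation likelihood
#'
#' Each particle's patch is cropped and warped under its state, sparse-coded
#' over the dictionary, and weighted by `exp(-lambda_lik * err)` where `err`
#' is the target-template projection error (the tracking result is the
#' candidate with the smallest such error). If the trivial-coefficient L1
#' energy of a particle exceeds the occlusion threshold, that particle is
#' re-coded with the trivial penalty multiplied by the occlusion weight.
#' Particles mapping entirely outside the frame get weight 0.
#'
#' @param frame [us_frame] or matrix.
#' @param particles List with `states`, `weights`.
#' @param dict [template_dictionary()].
#' @param params [pf_params()].
#' @return Particle set with normalised weights; attributes `err` and
#'   `occluded` carry diagnostics.
#' @export
update_weights <- function(frame, particles, dict, params = pf_params()) {
  img <- if (inherits(frame, "us_frame")) frame$pixels else as.matrix(frame)
  st <- particles$states
  ex <- extract_patches(img, st, params)
  X <- l2_normalize_cols(ex$X)
  sc <- sparse_code(X, dict, params)
  occ <- sc$trivial_l1 > params$occlusion_threshold * colSums(abs(X))
  if (any(occ)) {
    sc2 <- sparse_code(X[, occ, drop = FALSE], dict, params,
                       lambda_trivial = params$lambda_trivial * params$occlusion_weight)
    sc$err_target[occ] <- sc2$err_target
  }
  w <- exp(-params$lambda_lik * sc$err_target)
  w[ex$frac_outside >= 1] <- 0
  sw <- sum(w)
  if (sw > 0) w <- w / sw
  out <- list(states = st, weights = w)
  attr(out, "err") <- sc$err_target
  attr(out, "occluded") <- occ
  out
}

#' Systematic resampling of a particle set
#'
#' Samples with replacement according to the importance weights using the
#' systematic (stratified comb) scheme; the expected copy count of particle
#' i is `M * w_i`. Returns equally weighted particles.
#'
#' @param particles List with `states`, `weights` (normalised).
#' @return Particle set with uniform weights.
#' @export
pf_resample <- function(particles) {
  w <- particles$weights
  M <- length(w)
  if (sum(w) <= 0) stop("tracker lost target: all particle weights zero", call. = FALSE)
  w <- w / sum(w)
  cw <- cumsum(w)
  u <- (runif(1) + 0:(M - 1)) / M
  idx <- findInterval(u, cw, left.open = TRUE) + 1L
  idx[idx > M] <- M
  list(states = particles$states[idx, , drop = FALSE],
       weights = rep(1 / M, M))
}

#' Track an aponeurosis box across a video with the particle filter
#'
#' The dictionary is built from the frame-0 box content (plus jittered
#' crops) and kept static. Frames are pre-blurred with `obs_blur_sigma`
#' before patch extraction. For every subsequent frame the filter predicts,
#' re-weights, emits the posterior-mean state (the conditional expectation,
#' the optimal estimator of the Bayesian formulation; the
#' maximum-a-posteriori particle's error is kept as a diagnostic), and
#' resamples. Frame 0 emits the initialization box unchanged.
#'
#' @param video A [us_video].
#' @param init_box 4x2 initialization box (parallelogram corners).
#' @param params [pf_params()].
#' @return List: `boxes` (list of 4x2 matrices per frame), `states` (T x 6
#'   posterior-mean states), `diagnostics` (tibble with per-frame best error
#'   and occlusion flag).
#' @export
track_box <- function(video, init_box, params = pf_params()) {
  stopifnot(inherits(video, "us_video"))
  n <- length(video$frames)
  obs <- lapply(video$frames, function(f) {
    if (params$obs_blur_sigma > 0) gaussian_blur(f$pixels, params$obs_blur_sigma)
    else f$pixels
  })
  dict <- template_dictionary(obs[[1]], init_box, params)
  state0 <- dict$state0
  M <- params$n_particles
  particles <- list(
    states = matrix(rep(as.numeric(state0), each = M), nrow = M,
                    dimnames = list(NULL, state_names)),
    weights = rep(1 / M, M)
  )
  boxes <- vector("list", n)
  states <- matrix(NA_real_, n, 6, dimnames = list(NULL, state_names))
  err <- rep(NA_real_, n)
  occl <- rep(FALSE, n)
  boxes[[1]] <- box_from_state(state0, params$template_size)
  states[1, ] <- as.numeric(state0)
  if (n > 1) {
    for (t in 2:n) {
      particles <- pf_predict(particles, params)
      particles <- update_weights(obs[[t]], particles, dict, params)
      imax <- which.max(particles$weights)
      states[t, ] <- colSums(particles$states * particles$weights)
      boxes[[t]] <- box_from_state(states[t, ], params$template_size)
      err[t] <- attr(particles, "err")[imax]
      occl[t] <- attr(particles, "occluded")[imax]
      particles <- pf_resample(particles)
    }
  }
  list(boxes = boxes, states = states,
       diagnostics = tibble::tibble(frame = seq_len(n) - 1L, map_error = err,
                                    occluded = occl))
}
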