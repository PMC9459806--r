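# Independent oracles and small shared fixtures used across the test files.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Independent lasso oracle: cyclic coordinate descent on
#   0.5 ||x - D z||^2 + sum_i lambda_i |z_i|,  z_j >= 0 for j in `nonneg`.
# Deliberately a different algorithm from the package's proximal-gradient
# coder; used to verify the reconstruction error at convergence.
lasso_cd <- function(x, D, lambda, nonneg = integer(0), max_sweeps = 20000,
                     tol = 1e-12) {
  p <- ncol(D)
  z <- numeric(p)
  d2 <- colSums(D^2)
  r <- x
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (d2[j] == 0) next
      rho <- sum(D[, j] * r) + d2[j] * z[j]
      znew <- sign(rho) * max(abs(rho) - lambda[j], 0) / d2[j]
      if (j %in% nonneg) znew <- max(znew, 0)
      if (znew != z[j]) {
        r <- r - D[, j] * (znew - z[j])
        delta <- max(delta, abs(znew - z[j]))
        z[j] <- znew
      }
    }
    if (delta < tol) break
  }
  list(z = z, recon_err = sum((x - D %*% z)^2))
}

# Full explicit dictionary [T, I, -I] matching the package's implicit one.
full_dictionary <- function(Tm) {
  n <- nrow(Tm)
  cbind(Tm, diag(n), -diag(n))
}

# Small, quick-to-render phantom used by several unit tests.
tiny_phantom <- function(n_frames = 3L, speckle_sigma = 0, seed = 1L,
                         motion = list(type = "static")) {
  phantom_spec(image_shape = c(160L, 240L), mm_per_pixel = 0.25,
               pa0 = 20, fl0 = 36, deep_y = 120, band_thickness = 11,
               n_frames = n_frames, speckle_sigma = speckle_sigma,
               motion = motion, seed = seed)
}

# Reduced-size particle filter for unit tests that only exercise mechanics.
fast_pf <- function(...) pf_params(n_particles = 150L, ...)

fast_pipeline <- function() {
  pipeline_params(pf = fast_pf(), kaze = kaze_params(max_points = 80L))
}
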