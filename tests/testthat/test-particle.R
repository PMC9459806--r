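# Particle filter: affine warps, transition model, sparse coding, weighting,
# resampling, and box tracking.

test_that("state_to_warp composes the affine factors correctly", {
  idm <- state_to_warp(c(0, 0, 0, 1, 1, 0))
  expect_equal(idm, cbind(diag(2), c(0, 0)))
  tr <- state_to_warp(c(5, -3, 0, 1, 1, 0))
  expect_equal(tr, cbind(diag(2), c(5, -3)))

  # warp then inverse-warp is the identity
  st <- c(3.2, -1.5, 0.2, 1.3, 0.8, 0.1)
  M <- rbind(state_to_warp(st), c(0, 0, 1))
  p <- c(7, -4)
  q <- (M %*% c(p, 1))[1:2]
  back <- solve(M) %*% c(q, 1)
  expect_lt(max(abs(back[1:2] - p)), 1e-10)
})

test_that("box -> state -> box is a faithful round trip", {
  box <- rbind(c(10, 50), c(200, 54), c(201, 74), c(11, 70))
  st <- fasctrack:::state_from_box(box, c(39, 39))
  back <- fasctrack:::box_from_state(st, c(39, 39))
  expect_lt(max(abs(back - box)), 1e-8)
})

test_that("transition model perturbs each parameter with the configured variance", {
  M <- 10000L
  st0 <- c(100, 50, 0, 2, 0.5, 0)
  particles <- list(states = matrix(rep(st0, each = M), nrow = M),
                    weights = rep(1 / M, M))
  # zero variance: unchanged
  p0 <- pf_params(n_particles = M, variances = c(x = 0, y = 0, theta = 0,
                                                 s = 0, a = 0, psi = 0))
  expect_identical(pf_predict(particles, p0)$states, particles$states)

  set.seed(10)
  pv <- pf_params(n_particles = M, variances = c(x = 0.03, y = 0, theta = 0,
                                                 s = 0, a = 0, psi = 0))
  pred <- pf_predict(particles, pv)
  dx <- pred$states[, 1] - st0[1]
  # sample variance within chi-square-style bounds around 0.03
  expect_gt(var(dx), 0.025)
  expect_lt(var(dx), 0.035)
  # CLT bound on the mean of propagated states
  expect_lt(abs(mean(pred$states[, 1]) - st0[1]), 3 * sqrt(0.03 / M))
  expect_identical(pred$weights, particles$weights)
})

test_that("sparse coding identifies the matching atom and keeps the descent property", {
  set.seed(20)
  n <- 64
  Tm <- qr.Q(qr(matrix(rnorm(n * 6), n, 6)))       # orthonormal atoms
  Tm <- sweep(Tm, 2, sign(colSums(Tm)), "*")       # fix signs
  dict <- structure(list(templates = Tm), class = "template_dictionary")
  par <- pf_params()
  x <- Tm[, 3]
  # at the operational iteration budget the matching atom dominates; with a
  # long budget the cheap trivial templates absorb the whole patch instead
  sc <- sparse_code(x, dict, par)
  expect_equal(which.max(sc$coef_target), 3L)
  expect_true(all(sc$coef_target[-3] == 0))
  expect_lt(sc$err_total[1], 0.05)
  # mismatched patch reconstructs much worse through the target atoms
  y <- rnorm(n); y <- y / sqrt(sum(y^2))
  expect_gt(sparse_code(y, dict, par)$err_target[1], sc$err_target[1] + 0.3)

  # zero patch codes to (almost) nothing
  z <- sparse_code(numeric(n), dict, par)
  expect_lt(sum(abs(z$coef_target)) + sum(abs(z$coef_trivial)), 1e-8)
  expect_lt(z$err_total[1], 1e-12)

  # objective after coding <= objective of the all-zero code (0.5 ||x||^2)
  x2 <- rnorm(n); x2 <- x2 / sqrt(sum(x2^2))
  sc2 <- sparse_code(x2, dict, par)
  obj <- 0.5 * sc2$err_total[1] + par$lambda_target * sum(sc2$coef_target) +
    par$lambda_trivial * sum(abs(sc2$coef_trivial))
  expect_lte(obj, 0.5 * sum(x2^2))
})

test_that("proximal-gradient coding matches an independent lasso solver", {
  set.seed(21)
  par <- pf_params()
  for (i in 1:5) {
    n <- 30
    Tm <- matrix(rnorm(n * 5), n, 5)
    Tm <- sweep(Tm, 2, sqrt(colSums(Tm^2)), "/")
    dict <- structure(list(templates = Tm), class = "template_dictionary")
    x <- rnorm(n); x <- x / sqrt(sum(x^2))
    sc <- sparse_code(x, dict, par, max_iter = 200)
    D <- full_dictionary(Tm)
    lam <- c(rep(par$lambda_target, 5), rep(par$lambda_trivial, 2 * n))
    or <- lasso_cd(x, D, lam, nonneg = 1:5)
    expect_lt(abs(sc$err_total[1] - or$recon_err), 1e-6)
  }
})

test_that("weights are uniform for identical particles and zero out of frame", {
  spec <- tiny_phantom(n_frames = 1)
  img <- render_frame(spec, 0)$pixels
  boxes <- fasctrack:::boxes_from_init(make_init(spec))
  par <- fast_pf()
  dict <- template_dictionary(img, boxes$deep, par)
  M <- 12L
  st <- matrix(rep(as.numeric(dict$state0), each = M), nrow = M)
  p <- list(states = st, weights = rep(1 / M, M))
  up <- update_weights(img, p, dict, par)
  expect_equal(up$weights, rep(1 / M, M), tolerance = 1e-12)
  expect_equal(sum(up$weights), 1, tolerance = 1e-9)

  st2 <- st
  st2[5, 1:2] <- c(-4000, -4000)
  up2 <- update_weights(img, list(states = st2, weights = p$weights), dict, par)
  expect_equal(up2$weights[5], 0)
  expect_equal(sum(up2$weights), 1, tolerance = 1e-9)
})

test_that("the frame-0 box at the identity state carries the maximal weight", {
  spec <- tiny_phantom(n_frames = 1, speckle_sigma = 0.05, seed = 3)
  img <- render_frame(spec, 0)$pixels
  boxes <- fasctrack:::boxes_from_init(make_init(spec))
  par <- fast_pf()
  dict <- template_dictionary(img, boxes$deep, par)
  set.seed(30)
  M <- 40L
  st <- matrix(rep(as.numeric(dict$state0), each = M), nrow = M)
  st[-1, 2] <- st[-1, 2] + runif(M - 1, 2, 8) * sign(rnorm(M - 1))
  up <- update_weights(img, list(states = st, weights = rep(1 / M, M)), dict, par)
  expect_equal(which.max(up$weights), 1L)
})

test_that("systematic resampling reproduces the expected copy counts", {
  st <- matrix(seq_len(10), 10, 6)
  one <- list(states = st, weights = c(rep(0, 4), 1, rep(0, 5)))
  set.seed(40)
  r1 <- pf_resample(one)
  expect_true(all(r1$states[, 1] == 5))
  expect_equal(r1$weights, rep(0.1, 10))

  two <- list(states = st, weights = c(0.5, 0.5, rep(0, 8)))
  r2 <- pf_resample(two)
  expect_true(all(r2$states[, 1] %in% c(1, 2)))

  # uniform weights: mean copy count 1 over many seeds
  unif <- list(states = st, weights = rep(0.1, 10))
  counts <- matrix(0, 200, 10)
  set.seed(41)
  for (k in 1:200) {
    rk <- pf_resample(unif)
    counts[k, ] <- tabulate(rk$states[, 1], 10)
  }
  expect_lt(max(abs(colMeans(counts) - 1)), 0.2)

  none <- list(states = st, weights = rep(0, 10))
  expect_error(pf_resample(none), "lost target")
})

test_that("zero-variance tracking of a static video is a constant trajectory", {
  spec <- tiny_phantom(n_frames = 4, speckle_sigma = 0.05)
  vid <- phantom_video(spec)
  boxes <- fasctrack:::boxes_from_init(make_init(spec))
  par <- pf_params(n_particles = 50L,
                   variances = c(x = 0, y = 0, theta = 0, s = 0, a = 0, psi = 0))
  set.seed(50)
  tr <- track_box(vid, boxes$deep, par)
  for (t in 2:4) expect_equal(tr$boxes[[t]], tr$boxes[[1]], tolerance = 1e-9)
})

test_that("a single-frame video returns the initialization box unchanged", {
  spec <- tiny_phantom(n_frames = 1)
  vid <- phantom_video(spec)
  boxes <- fasctrack:::boxes_from_init(make_init(spec))
  tr <- track_box(vid, boxes$deep, fast_pf())
  expect_equal(tr$boxes[[1]], unname(boxes$deep), tolerance = 1e-8)
  expect_length(tr$boxes, 1L)
})

test_that("static-video tracking stays near the initialization box", {
  spec <- tiny_phantom(n_frames = 5, speckle_sigma = 0.1, seed = 12)
  vid <- phantom_video(spec)
  boxes <- fasctrack:::boxes_from_init(make_init(spec))
  set.seed(60)
  tr <- track_box(vid, boxes$deep)
  ctr <- t(vapply(tr$boxes, colMeans, numeric(2)))
  dev <- sweep(ctr, 2, ctr[1, ])
  expect_lt(max(abs(dev)), 1)
})
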