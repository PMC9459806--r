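# Fascicle-band distortion tracking: ROI, interest points, optical flow,
# robust affine estimation, line propagation.

test_that("ROI construction normalises corners and rejects degenerate spans", {
  roi <- define_roi(c(10, 50), c(60, 120))
  expect_equal(c(roi$x, roi$y, roi$width, roi$height), c(10, 50, 50, 70))
  roi2 <- define_roi(c(60, 50), c(10, 120))
  expect_equal(c(roi2$x, roi2$y, roi2$width, roi2$height), c(10, 50, 50, 70))
  expect_error(define_roi(c(10, 50), c(10, 120)), "zero-width")
})

test_that("interest-point detection needs texture and is deterministic", {
  flat <- matrix(0.5, 120, 160)
  expect_error(detect_kaze(flat), "texture")

  spec <- tiny_phantom(n_frames = 1, speckle_sigma = 0.1)
  f <- render_frame(spec, 0)
  ins <- attr(ground_truth(spec), "insertions")
  roi <- define_roi(ins[1, c("ax", "ay")], ins[1, c("bx", "by")], spec$image_shape)
  pts <- detect_kaze(f, roi)
  expect_gte(nrow(pts), 20)
  expect_true(all(pts[, "x"] >= roi$x & pts[, "x"] <= roi$x + roi$width))
  expect_true(all(pts[, "y"] >= roi$y & pts[, "y"] <= roi$y + roi$height))
  expect_identical(pts, detect_kaze(f, roi))
})

test_that("point tracking recovers known displacements and flags occlusion", {
  spec <- tiny_phantom(n_frames = 1, speckle_sigma = 0.1, seed = 6)
  f <- render_frame(spec, 0)$pixels
  # identical frames: zero displacement, all valid
  set.seed(1)
  pts <- cbind(x = runif(15, 40, 200), y = runif(15, 60, 110))
  same <- track_points(f, f, pts, klt_params(), 0.25)
  expect_true(all(same$valid))
  expect_lt(max(abs(same$points - pts)), 0.05)

  # integer translation by (3, 2)
  g <- matrix(0, nrow(f), ncol(f))
  g[3:nrow(f), 4:ncol(f)] <- f[1:(nrow(f) - 2), 1:(ncol(f) - 3)]
  tr <- track_points(f, g, pts, klt_params(), 0.25)
  d <- tr$points[tr$valid, ] - pts[tr$valid, ]
  expect_gte(sum(tr$valid), 10)
  expect_lt(max(abs(colMeans(d) - c(3, 2))), 0.5)

  # occlusion: texture replaced by a constant patch in the tracked frame
  h <- f
  h[55:115, 80:160] <- 0.5
  occl_pt <- cbind(x = 120, y = 85)
  occl <- track_points(f, h, occl_pt, klt_params(), 0.25)
  expect_false(occl$valid[1])
})

test_that("bidirectional tolerance only ever adds valid points", {
  spec <- tiny_phantom(n_frames = 2, speckle_sigma = 0.15,
                       motion = list(type = "translate", delta = c(1, 1)))
  f0 <- render_frame(spec, 0); f1 <- render_frame(spec, 1)
  set.seed(2)
  pts <- cbind(x = runif(25, 30, 210), y = runif(25, 55, 115))
  v1 <- track_points(f0, f1, pts, klt_params(max_bidir_error_mm = 0.1), 0.25)$valid
  v2 <- track_points(f0, f1, pts, klt_params(max_bidir_error_mm = 3), 0.25)$valid
  expect_gte(sum(v2), sum(v1))
  expect_true(all(v2[v1]))
})

test_that("MSAC recovers exact affines and rejects gross outliers", {
  set.seed(3)
  src <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  M <- rbind(c(1.1, 0.1, 5), c(-0.05, 0.95, -3))
  dst <- fasctrack:::apply_affine(M, src)
  fit <- estimate_affine_msac(src, dst)
  expect_lt(max(abs(fit$transform - M)), 1e-6)
  expect_true(all(fit$inliers))

  dst2 <- dst
  dst2[1:3, ] <- dst2[1:3, ] + 100
  fit2 <- estimate_affine_msac(src, dst2)
  expect_false(any(fit2$inliers[1:3]))
  expect_true(all(fit2$inliers[4:10]))
  expect_lt(max(abs(fit2$transform - M)), 1e-4)

  idp <- cbind(runif(5, 0, 10), runif(5, 0, 10))
  fit3 <- estimate_affine_msac(idp, idp)
  expect_lt(max(abs(fit3$transform - cbind(diag(2), c(0, 0)))), 1e-8)
  expect_error(estimate_affine_msac(src[1:2, ], dst[1:2, ]), "at least 3")
})

test_that("MSAC agrees with least squares on outlier-free noisy data", {
  set.seed(4)
  src <- cbind(runif(30, 0, 200), runif(30, 0, 100))
  M <- rbind(c(1.02, 0.03, -2), c(0.01, 0.97, 4))
  dst <- fasctrack:::apply_affine(M, src) + matrix(rnorm(60, 0, 0.3), 30, 2)
  fit <- estimate_affine_msac(src, dst)
  ls <- fasctrack:::affine_lsfit(src, dst)
  expect_lt(max(abs(fit$transform - ls)), 1e-6)
})

test_that("line propagation is exact for rigid and scaling transforms", {
  seg <- rbind(c(10, 20), c(30, 40))
  idm <- cbind(diag(2), c(0, 0))
  expect_equal(propagate_line(seg, idm), seg)

  th <- 10 * pi / 180
  mid <- colMeans(seg)
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  Mrot <- cbind(R, mid - R %*% mid)
  out <- propagate_line(seg, Mrot)
  expect_equal(sqrt(sum((out[2, ] - out[1, ])^2)),
               sqrt(sum((seg[2, ] - seg[1, ])^2)), tolerance = 1e-9)
  a0 <- atan2(seg[2, 2] - seg[1, 2], seg[2, 1] - seg[1, 1])
  a1 <- atan2(out[2, 2] - out[1, 2], out[2, 1] - out[1, 1])
  expect_equal(a1 - a0, th, tolerance = 1e-9)

  expect_equal(propagate_line(seg, cbind(2 * diag(2), c(0, 0))), 2 * seg)
})

test_that("one distortion step recovers a known global affine and composition is consistent", {
  spec <- phantom_spec(image_shape = c(160L, 240L), mm_per_pixel = 0.25,
                       pa0 = 20, fl0 = 36, deep_y = 120, band_thickness = 11,
                       n_frames = 3, speckle_sigma = 0.1, seed = 8,
                       motion = list(type = "contraction", pa1 = 21.5, fl1 = 34.8))
  gt <- ground_truth(spec)
  aff <- attr(gt, "affines")
  ins <- attr(gt, "insertions")
  frames <- lapply(0:2, function(t) render_frame(spec, t))
  step <- function(t) { # track frame t -> t+1, return estimated transform
    A <- ins[t + 1, c("ax", "ay")]; B <- ins[t + 1, c("bx", "by")]
    roi <- define_roi(A, B, spec$image_shape)
    pts <- detect_kaze(frames[[t + 1]], roi)
    tr <- track_points(frames[[t + 1]], frames[[t + 2]], pts[, 1:2],
                       klt_params(), spec$mm_per_pixel)
    estimate_affine_msac(pts[tr$valid, 1:2], tr$points[tr$valid, ])$transform
  }
  set.seed(5)
  T01 <- step(0)
  ef0 <- rbind(ins[1, c("ax", "ay")], ins[1, c("bx", "by")])
  ef1_true <- rbind(ins[2, c("ax", "ay")], ins[2, c("bx", "by")])
  ef1 <- propagate_line(ef0, T01)
  expect_lt(max(abs(ef1 - ef1_true)), 1)

  # composing two estimated steps lands within 1.5 px of the direct truth
  T12 <- step(1)
  ef2 <- propagate_line(propagate_line(ef0, T01), T12)
  ef2_true <- rbind(ins[3, c("ax", "ay")], ins[3, c("bx", "by")])
  expect_lt(max(abs(ef2 - ef2_true)), 1.5)
})
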