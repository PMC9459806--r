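# Chan-Vese level-set segmentation, boundary isolation, and line fitting.

make_bar_image <- function(nr = 64, nc = 64, rows = 25:40, fg = 1, bg = 0) {
  img <- matrix(bg, nr, nc)
  img[rows, ] <- fg
  img
}

test_that("init_level_set has the signed-distance sign convention", {
  frame <- matrix(0, 64, 64)
  box <- rbind(c(10, 10), c(50, 10), c(50, 20), c(10, 20))
  phi <- init_level_set(frame, box)
  expect_gt(phi[16, 31], 0)   # (x=30, y=15) inside
  expect_lt(phi[1, 1], 0)     # (0, 0) outside
  # phi ~ 0 on the box edge
  expect_lt(abs(phi[11, 31]), 0.5)  # (30, 10) on the top edge
  # box covering the whole frame: interior everywhere away from the margin
  phi2 <- init_level_set(frame, rbind(c(-1, -1), c(64, -1), c(64, 64), c(-1, 64)))
  expect_true(all(phi2 >= 0))
  expect_error(init_level_set(frame, rbind(c(100, 100), c(120, 100), c(120, 110), c(100, 110))),
               "outside")
})

test_that("evolution recovers a two-value band and tolerates speckle", {
  img <- make_bar_image()
  truth <- img > 0.5
  box <- rbind(c(0, 22), c(63, 22), c(63, 43), c(0, 43))
  ev <- evolve_mcv(img, init_level_set(img, box))
  expect_gte(dice_coef(ev$phi > 0, truth), 0.99)
  expect_lte(ev$iterations, mcv_params()$max_iter)
  # endpoint energy improvement (BB is non-monotone per-iteration)
  expect_lte(tail(ev$energy_trace, 1), ev$energy_trace[1])

  set.seed(42)
  noisy <- pmin(pmax(img * (1 + 0.2 * matrix(rnorm(length(img)), nrow(img))) +
                       0.05, 0), 1)
  ev2 <- evolve_mcv(noisy, init_level_set(noisy, box))
  expect_gte(dice_coef(ev2$phi > 0, truth), 0.95)
})

test_that("evolution handles a constant image without error", {
  img <- matrix(0.5, 48, 48)
  box <- rbind(c(10, 10), c(38, 10), c(38, 30), c(10, 30))
  ev <- evolve_mcv(img, init_level_set(img, box))
  expect_true(is.finite(tail(ev$energy_trace, 1)))
  expect_lte(ev$iterations, mcv_params()$max_iter)
})

test_that("segmentation is invariant to affine intensity rescaling", {
  img <- make_bar_image(fg = 0.8, bg = 0.1)
  box <- rbind(c(0, 20), c(63, 20), c(63, 45), c(0, 45))
  m1 <- evolve_mcv(img, init_level_set(img, box))$phi > 0
  m2 <- evolve_mcv(0.55 * img + 0.2, init_level_set(img, box))$phi > 0
  expect_identical(m1, m2)
})

test_that("band boundary extraction picks the band-facing edge and the largest component", {
  mask <- matrix(FALSE, 64, 64)
  mask[11:15, ] <- TRUE     # bar rows y = 10..14, all 64 columns
  b_sup <- extract_band_boundary(mask, "superficial")
  expect_equal(nrow(b_sup), 64)
  expect_true(all(b_sup[, "y"] == 14))
  b_deep <- extract_band_boundary(mask, "deep")
  expect_true(all(b_deep[, "y"] == 10))

  # second small component is ignored
  mask2 <- mask
  mask2[40:44, 10:13] <- TRUE  # 20 px blob vs 320 px bar
  b2 <- extract_band_boundary(mask2, "deep")
  expect_true(all(b2[, "y"] == 10))
  expect_error(extract_band_boundary(matrix(FALSE, 8, 8), "deep"), "empty")
  m1col <- matrix(FALSE, 8, 8); m1col[3:5, 4] <- TRUE
  expect_error(extract_band_boundary(m1col, "deep"), "fewer than 2")
})

test_that("boundary line fitting is exact on lines and robust to symmetric noise", {
  x <- 0:20
  exact <- fit_boundary_line(cbind(x = x, y = 2 * x + 3))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 3)
  expect_equal(exact$n_support, 21L)

  # alternating +/- 1 px noise around y = 5 (closed-form OLS: slope 0 within 0.1)
  x2 <- 0:39
  noisy <- fit_boundary_line(cbind(x = x2, y = 5 + rep(c(1, -1), 20)))
  expect_lt(abs(noisy$slope), 0.1)
  expect_lt(abs(noisy$intercept - 5), 0.1)

  expect_error(fit_boundary_line(cbind(x = rep(3, 5), y = 1:5)), "degenerate")
  steep <- cbind(x = c(0, 0, 1, 1), y = c(0, 1, 50, 51))
  expect_error(fit_boundary_line(steep), "near-vertical")
})

test_that("delineation recovers exact band edges on noiseless phantoms", {
  spec <- tiny_phantom()
  f0 <- render_frame(spec, 0)
  boxes <- fasctrack:::boxes_from_init(make_init(spec))
  deep <- delineate_boundary(f0, boxes$deep, "deep")$line
  expect_lt(abs(deep$slope - spec$deep_inner[1]), 0.02)
  expect_lt(abs(deep$intercept - spec$deep_inner[2]), 0.5)
  sup <- delineate_boundary(f0, boxes$superficial, "superficial")$line
  expect_lt(abs(sup$slope - spec$sup_inner[1]), 0.02)
  expect_lt(abs(sup$intercept - spec$sup_inner[2]), 0.5)
})
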