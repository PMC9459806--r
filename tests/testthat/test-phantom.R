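# Synthetic phantom generator: rendering, ground truth, initialization.

test_that("noiseless rendering draws exact band intensities and is deterministic", {
  spec <- tiny_phantom(n_frames = 2)
  f0 <- render_frame(spec, 0)
  band <- phantom_band_mask(spec, 0, "deep")
  core <- band & phantom_band_mask(spec, 0, "deep")  # interior incl. edges
  # interior rows (excluding the anti-aliased edge rows) are exactly the band intensity
  interior <- matrix(FALSE, nrow(f0$pixels), ncol(f0$pixels))
  interior[(spec$deep_inner[2] + 2):(spec$deep_inner[2] + spec$band_thickness - 2) + 1, ] <- TRUE
  expect_true(all(f0$pixels[interior] == spec$band_intensity))

  s2 <- tiny_phantom(n_frames = 2, speckle_sigma = 0.2, seed = 9)
  expect_identical(render_frame(s2, 1)$pixels, render_frame(s2, 1)$pixels)
  expect_identical(
    render_frame(tiny_phantom(speckle_sigma = 0.2, seed = 9), 0)$pixels,
    render_frame(tiny_phantom(speckle_sigma = 0.2, seed = 9), 0)$pixels
  )
})

test_that("mean band intensity is preserved under speckle", {
  # band intensity kept away from 1 so the [0, 1] clip does not truncate
  # the multiplicative noise distribution
  spec <- phantom_spec(image_shape = c(160L, 240L), mm_per_pixel = 0.25,
                       pa0 = 20, fl0 = 36, deep_y = 120, band_thickness = 11,
                       band_intensity = 0.6, n_frames = 1,
                       speckle_sigma = 0.2, seed = 4)
  f <- render_frame(spec, 0)
  # fully covered band rows (the anti-aliased edge rows carry half weight)
  band <- matrix(FALSE, nrow(f$pixels), ncol(f$pixels))
  band[(spec$deep_inner[2] + 1):(spec$deep_inner[2] + spec$band_thickness - 1) + 1, ] <- TRUE
  expect_lt(abs(mean(f$pixels[band]) - spec$band_intensity) / spec$band_intensity, 0.02)
})

test_that("ground truth follows the scheduled geometry", {
  expect_equal(ground_truth(tiny_phantom(n_frames = 4))$fl_mm, rep(36, 4))
  expect_equal(ground_truth(tiny_phantom(n_frames = 4))$pa_deg, rep(20, 4))

  spec <- phantom_spec(n_frames = 30, motion = list(type = "contraction", pa1 = 30, fl1 = 40))
  gt <- ground_truth(spec)
  expect_equal(gt$pa_deg, 20 + 10 * (0:29) / 29, tolerance = 1e-9)
  expect_equal(gt$fl_mm, 50 - 10 * (0:29) / 29, tolerance = 1e-9)
  expect_equal(gt$pa_deg[16], 20 + 10 * 15 / 29)

  tr <- ground_truth(tiny_phantom(n_frames = 5,
                                  motion = list(type = "translate", delta = c(1.5, -0.5))))
  expect_equal(tr$fl_mm, rep(36, 5))
  expect_equal(tr$pa_deg, rep(20, 5))
})

test_that("rendered geometry and ground truth are mutually consistent", {
  # threshold the noiseless frame directly and intersect with the true
  # fascicle line: must reproduce the analytic ground truth
  spec <- tiny_phantom(n_frames = 1)
  f <- render_frame(spec, 0)
  ins <- attr(ground_truth(spec), "insertions")
  thr <- (spec$band_intensity + spec$background) / 2
  deep_rows <- vapply(seq_len(ncol(f$pixels)), function(j) {
    col <- f$pixels[, j]
    r <- which(col >= thr)
    r <- r[r - 1 >= spec$deep_inner[2] - 2]  # deep band only
    y1 <- min(r)                             # first in-band row (1-based)
    # subpixel crossing of the threshold between y1-1 and y1
    (y1 - 2) + (thr - col[y1 - 1]) / (col[y1] - col[y1 - 1])
  }, numeric(1))
  line <- fit_boundary_line(cbind(x = 0:(ncol(f$pixels) - 1), y = deep_rows))
  B <- intersect_line_boundary(rbind(ins[1, c("ax", "ay")], ins[1, c("bx", "by")]), line)
  expect_lt(max(abs(B - ins[1, c("bx", "by")])), 0.5)
})

test_that("make_init encloses the bands and aligns EF with the fascicles", {
  spec <- tiny_phantom()
  ini <- make_init(spec)
  boxes <- fasctrack:::boxes_from_init(ini)
  for (side in c("superficial", "deep")) {
    band <- phantom_band_mask(spec, 0, side)
    mask <- matrix(FALSE, spec$image_shape[1], spec$image_shape[2])
    b <- boxes[[side]]
    xr <- round(range(b[, 1])); yr <- round(range(b[, 2]))
    mask[(yr[1]:yr[2]) + 1, (xr[1]:xr[2]) + 1] <- TRUE
    expect_gte(sum(band & mask) / sum(band), 0.9)
  }
  u <- ini$fascicle_line[2, ] - ini$fascicle_line[1, ]
  ang <- abs(atan2(u[2], u[1]) * 180 / pi + spec$pa0)
  expect_lt(ang, 1e-6)
})

test_that("init perturbations pass through as specified", {
  spec <- tiny_phantom()
  ref <- make_init(spec)
  sh <- make_init(spec, shift_px = 10)
  expect_equal(unname(sh$fascicle_line - ref$fascicle_line),
               matrix(c(10, 10, 0, 0), 2, 2), tolerance = 1e-9)
  th <- make_init(spec, thickness_delta = 3)
  expect_equal(th$deep_thickness, ref$deep_thickness + 3)
  rot <- make_init(spec, rotate_px = 5)
  # E and F move in opposite directions; midpoint preserved
  expect_equal(colMeans(rot$fascicle_line), colMeans(ref$fascicle_line),
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(rot$fascicle_line, ref$fascicle_line)))
})

test_that("invalid phantom geometry is rejected at construction", {
  expect_error(tiny_phantom(motion = list(type = "warp")), "unknown motion")
  # contraction pushing insertions out of the image
  expect_error(
    phantom_spec(image_shape = c(160L, 200L), mm_per_pixel = 0.25, pa0 = 20,
                 fl0 = 44, deep_y = 120, band_thickness = 11, n_frames = 10,
                 motion = list(type = "contraction", pa1 = 55, fl1 = 60)),
    "outside the image|bounds"
  )
})
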