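test_that("plate images round-trip through PNG and 16-bit TIFF", {
  p <- generate_plate(plate_spec(seed = 2))
  png_path <- tempfile(fileext = ".png")
  tif_path <- tempfile(fileext = ".tif")
  write_plate_image(p, png_path)
  write_plate_image(p, tif_path)
  back8 <- load_plate_image(png_path, p$layout)
  back16 <- load_plate_image(tif_path, p$layout)
  expect_lt(max(abs(back8$pixels - p$pixels)), 1 / 255)
  expect_lt(max(abs(back16$pixels - p$pixels)), 1 / 65535)
  # pure white stays exactly 1
  wpath <- tempfile(fileext = ".png")
  png::writePNG(matrix(1, 20, 20), wpath)
  lay <- lane_layout(15, 3, c(5, 10), rs_amounts_ug = 1, test_lane_index = 2)
  expect_equal(max(load_plate_image(wpath, lay)$pixels), 1)
  unlink(c(png_path, tif_path, wpath))
})

test_that("layouts out of raster bounds or degenerate are rejected", {
  p <- generate_plate(plate_spec(seed = 2))
  path <- tempfile(fileext = ".png")
  write_plate_image(p, path)
  bad <- p$layout; bad$origin_y <- 10000L
  expect_error(load_plate_image(path, bad), "bounds")
  expect_error(lane_layout(50, 50, c(10, 20), rs_amounts_ug = 1,
                           test_lane_index = 2), "front_y")
  unlink(path)
})

test_that("layout sidecars round-trip through JSON", {
  lay <- lane_layout(170, 30, seq(40, 360, 40))
  path <- tempfile(fileext = ".json")
  write_layout(lay, path)
  expect_equal(read_layout(path), lay)
  unlink(path)
})

test_that("background of a uniform image is that constant everywhere", {
  lay <- lane_layout(40, 5, c(10, 30), rs_amounts_ug = 1, test_lane_index = 2)
  bg <- estimate_background(raw_plate(matrix(0.73, 50, 60), lay))
  expect_equal(as.vector(bg), rep(0.73, 3000), tolerance = 1e-12)
  expect_false(attr(bg, "low_confidence"))
})

test_that("background recovers a tilted field away from the spots", {
  spec <- plate_spec(noise_sd = 0, background_tilt = 0.05, seed = 4)
  p <- generate_plate(spec)
  est <- estimate_background(p)
  ramp <- (seq_len(spec$width_px) - 1) / (spec$width_px - 1) - 0.5
  true_bg <- matrix(0.9 + 0.05 * ramp, nrow = spec$height_px,
                    ncol = spec$width_px, byrow = TRUE)
  far <- matrix(TRUE, spec$height_px, spec$width_px)
  for (i in seq_len(nrow(p$truth))) {
    t <- p$truth[i, ]
    yy <- outer(seq_len(spec$height_px) - t$cy, rep(1, spec$width_px))
    xx <- outer(rep(1, spec$height_px), seq_len(spec$width_px) - t$cx)
    far <- far & (yy^2 + xx^2 > (3 * spec$spot_sigma_px)^2)
  }
  expect_lt(max(abs(est[far] - true_bg[far])), 0.02)
})

test_that("a mostly-dark scan is flagged low-confidence", {
  # elliptical blob over ~60% of the scan, misaligned with rows and columns
  m <- matrix(0.9, 50, 60)
  yy <- outer((seq_len(50) - 25.5) / 22, rep(1, 60))
  xx <- outer(rep(1, 50), (seq_len(60) - 30.5) / 26)
  m[yy^2 + xx^2 <= 1] <- 0.1
  lay <- lane_layout(40, 5, c(10, 30), rs_amounts_ug = 1, test_lane_index = 2)
  bg <- estimate_background(raw_plate(m, lay))
  expect_true(attr(bg, "low_confidence"))
})

test_that("detection finds every generated spot and nothing else", {
  for (seed in c(1, 12, 123)) {
    p <- generate_plate(plate_spec(seed = seed))
    det <- assign_lanes(detect_spots(p), p$layout)
    expect_equal(nrow(det), 9)
    det <- det[order(det$lane), ]
    expect_equal(det$lane, p$truth$lane)
    expect_true(all(abs(det$cx - p$truth$cx) < 1.5))
    expect_true(all(abs(det$cy - p$truth$cy) < 1.5))
    expect_true(all(abs(det$rf - p$truth$rf) < 0.02))
  }
  blank <- generate_plate(plate_spec(amounts_ug = rep(0, 9), seed = 1))
  expect_equal(nrow(detect_spots(blank)), 0)
})

test_that("two merging spots yield one detection flagged multi-peak", {
  h <- 100; w <- 120
  img <- matrix(1, h, w)
  for (cx in c(50, 68)) {
    gy <- exp(-((seq_len(h) - 50)^2) / (2 * 36))
    gx <- exp(-((seq_len(w) - cx)^2) / (2 * 36))
    img <- img - 0.4 * (gy %o% gx)
  }
  lay <- lane_layout(90, 10, c(59), rs_amounts_ug = numeric(0),
                     test_lane_index = 1)
  det <- detect_spots(raw_plate(pmax(img, 0), lay))
  expect_equal(nrow(det), 1)
  expect_gte(det$n_peaks[1], 2)
  expect_match(det$flags[1], "multi_peak")
})

test_that("retention factor is the migration fraction with flags outside", {
  lay <- lane_layout(170, 30, c(40), rs_amounts_ug = numeric(0),
                     test_lane_index = 1)
  expect_equal(compute_rf(170, lay), 0)
  expect_equal(compute_rf(30, lay), 1)
  expect_equal(compute_rf(100, lay), 0.5)
  expect_gt(compute_rf(10, lay), 1)   # beyond the front, allowed but > 1
  degen <- lay; degen$front_y <- degen$origin_y
  expect_error(compute_rf(100, degen), "degenerate")
})

test_that("lane assignment: nearest within half-width, ties to lower lane", {
  p <- generate_plate(plate_spec(seed = 1))
  det <- detect_spots(p)
  lay <- p$layout
  one <- det[1, ]
  one$cx <- lay$application_xs[4]
  expect_equal(assign_lanes(one, lay)$lane, 4L)
  one$cx <- mean(lay$application_xs[4:5])  # equidistant
  tied <- assign_lanes(one, lay)
  expect_equal(tied$lane, 4L)
  expect_match(tied$flags, "lane_tie")
  one$cx <- lay$application_xs[1] - lay$lane_half_width - 5
  expect_true(is.na(assign_lanes(one, lay)$lane))
})

test_that("detection is invariant to an affine rescale undone on input", {
  p <- generate_plate(plate_spec(seed = 8))
  d1 <- detect_spots(p)
  q <- p
  q$pixels <- (p$pixels * 0.5 + 0.25 - 0.25) / 0.5
  d2 <- detect_spots(q)
  expect_equal(d1$cx, d2$cx, tolerance = 1e-9)
  expect_equal(d1$area, d2$area)
})
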