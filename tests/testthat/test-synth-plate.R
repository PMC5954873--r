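test_that("a spotless, noiseless plate is exactly its background field", {
  spec <- plate_spec(amounts_ug = rep(0, 9), noise_sd = 0,
                     background_level = 0.9, background_tilt = 0.05)
  p <- generate_plate(spec)
  expect_equal(nrow(p$truth), 0)
  # oracle: the documented planar background, evaluated directly
  ramp <- (seq_len(spec$width_px) - 1) / (spec$width_px - 1) - 0.5
  bg <- matrix(0.9 + 0.05 * ramp, nrow = spec$height_px,
               ncol = spec$width_px, byrow = TRUE)
  expect_equal(p$pixels, bg, tolerance = 1e-12)
})

test_that("peak darkness follows the saturating-linear response per lane", {
  spec <- quiet_spec()
  p <- generate_plate(spec)
  expect_equal(nrow(p$truth), 9)
  # analytic oracle evaluated independently of the generator internals
  d_oracle <- function(a, s)
    pmin(pmax(s$darkness_intercept + s$darkness_slope *
                pmin(a, s$saturation_knee) +
                (s$darkness_slope / 8) * pmax(a - s$saturation_knee, 0),
              0), 1)
  expect_equal(p$truth$peak_darkness, d_oracle(spec$amounts_ug, spec))
  rs <- p$truth$peak_darkness[1:8]
  expect_true(all(diff(rs) > 0))
  # strictly linear on the declared 1.0-2.0 ug working range
  lin <- p$truth$amount_ug >= 1 & p$truth$amount_ug <= 2
  fit <- lm(p$truth$peak_darkness[lin] ~ p$truth$amount_ug[lin])
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("noiseless image equals background minus Gaussian deficits exactly", {
  spec <- quiet_spec(background_level = 0.95)
  p <- generate_plate(spec)
  h <- spec$height_px; w <- spec$width_px
  img <- matrix(0.95, h, w)
  for (i in seq_len(nrow(p$truth))) {
    t <- p$truth[i, ]
    gy <- exp(-((seq_len(h) - t$cy)^2) / (2 * spec$spot_sigma_px^2))
    gx <- exp(-((seq_len(w) - t$cx)^2) / (2 * spec$spot_sigma_px^2))
    img <- img - t$peak_darkness * (gy %o% gx)
  }
  expect_equal(p$pixels, pmin(pmax(img, 0), 1), tolerance = 1e-12)
})

test_that("seeding contract: same seed bit-identical, new seed differs", {
  p1 <- generate_plate(plate_spec(seed = 5))
  p2 <- generate_plate(plate_spec(seed = 5))
  p3 <- generate_plate(plate_spec(seed = 6))
  expect_identical(p1$pixels, p2$pixels)
  expect_false(identical(p1$pixels, p3$pixels))
})

test_that("pixels stay in [0,1] and ground-truth Rf matches the layout", {
  for (seed in 1:5) {
    spec <- plate_spec(seed = seed, rf_per_lane = 0.45)
    p <- generate_plate(spec)
    expect_true(all(p$pixels >= 0 & p$pixels <= 1))
    half_px <- 0.5 / (spec$origin_y - spec$front_y)
    expect_true(all(abs(p$truth$rf - 0.45) <= half_px + 1e-12))
  }
})

test_that("invalid specs are rejected", {
  expect_error(plate_spec(origin_y = 20, front_y = 170), "geometry")
  expect_error(plate_spec(rf_per_lane = 1.4), "rf_per_lane")
  expect_error(plate_spec(background_level = 0.99, background_tilt = 0.05),
               "background")
  expect_error(plate_spec(amounts_ug = c(seq(2.4, 1.0, by = -0.2), 2)),
               "strictly increasing")
  # lanes closer than 4 sigma overlap
  expect_error(plate_spec(application_xs = seq(40, 200, by = 20),
                          amounts_ug = c(seq(1, 2.4, 0.2), 2),
                          spot_sigma_px = 6),
               "spacing")
})

test_that("campaign replication: 12 plates per sample-API, 6 per system", {
  camp <- generate_campaign(demo_manifest(), seed = 3)
  expect_length(camp$plates, 12)
  systems <- vapply(camp$plates, function(p) p$meta$solvent_system_id, 1L)
  expect_equal(as.vector(table(systems)), c(6L, 6L))
  rf1 <- camp$plates[[1]]$spec$rf_per_lane[1]
  rf2 <- camp$plates[[12]]$spec$rf_per_lane[1]
  expect_false(rf1 == rf2)  # per-solvent-system migration differs
})

test_that("campaign size scales as samples x APIs x 12 and is seeded", {
  m <- rbind(demo_manifest(2, "ATM", 20), demo_manifest(2, "LUM", 120))
  camp <- generate_campaign(m, seed = 9)
  expect_length(camp$plates, 48)
  camp2 <- generate_campaign(m, seed = 9)
  expect_identical(camp$plates[[17]]$pixels, camp2$plates[[17]]$pixels)
  empty <- generate_campaign(demo_manifest(0), seed = 1)
  expect_length(empty$plates, 0)
})
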