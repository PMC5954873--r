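test_that("brighten is the clipped additive offset", {
  m <- matrix(c(0, 0.3, 0.7, 1), 2)
  expect_identical(brighten(m, 0), m)
  expect_equal(brighten(0.7, 0.4), 1)
  expect_equal(brighten(m, 0.2), pmin(m + 0.2, 1))
  expect_error(brighten(m, -0.1), ">= 0")
})

test_that("disappearance threshold matches the white-background closed form", {
  # spot of uniform intensity s on a white background: contrast after an
  # offset b is max(1 - s - b, 0), so b* is the first grid offset past
  # 1 - s - epsilon
  h <- 30; w <- 30
  white <- matrix(1, h, w)
  params <- fading_params(visibility_epsilon = 0.05)
  step <- params$brightness_step
  for (s in c(0.3, 0.2)) {
    img <- white; img[10:14, 10:14] <- s
    region <- which(img < 1)
    prof <- fading_threshold(img, white, region, params)
    closed <- 1 - s - 0.05
    expect_lte(abs(prof$b_star - closed), step + 1e-12)
    expect_false(prof$censored)
    expect_true(all(diff(prof$contrast) <= 1e-12))  # nonincreasing curve
  }
  # darker spot survives longer
  dark <- white; dark[5, 5] <- 0.2
  light <- white; light[5, 5] <- 0.3
  b_dark <- fading_threshold(dark, white, which(dark < 1), params)$b_star
  b_light <- fading_threshold(light, white, which(light < 1), params)$b_star
  expect_gt(b_dark, b_light)
  expect_error(fading_threshold(white, white, integer(0), params), "empty")
})

test_that("RS fading thresholds increase strictly on a noise-free plate", {
  p <- generate_plate(plate_spec(noise_sd = 0, seed = 3))
  est <- quantify_plate(p, 100)
  b <- est$audit$series$b_stars
  expect_length(b, 8)
  expect_true(all(diff(b) > 0))
  expect_true(est$audit$series$monotonic)
})

test_that("bracketing follows the reading rules, censoring at the ends", {
  a <- seq(1.0, 2.4, 0.2)
  b <- 0.3 + (a - 1) * 0.25           # clean increasing thresholds
  ser <- reference_series(a, b)
  par <- fading_params()
  # between the 1.4 and 1.6 lanes -> [1.4, 1.6] under both rules
  t_mid <- mean(b[3:4])
  for (rule in c("lower", "point")) {
    br <- bracket_estimate(t_mid, ser, par, tie_rule = rule)
    expect_equal(c(br$lower_ug, br$upper_ug), c(1.4, 1.6))
  }
  # simultaneous fade with the 2.0 lane: point rule pins it there,
  # the reading rule keeps the next RS up as the upper limit
  tie <- bracket_estimate(b[6], ser, par, tie_rule = "point")
  expect_equal(c(tie$lower_ug, tie$upper_ug), c(2.0, 2.0))
  low <- bracket_estimate(b[6], ser, par, tie_rule = "lower")
  expect_equal(c(low$lower_ug, low$upper_ug), c(2.0, 2.2))
  # beyond the ends
  hi <- bracket_estimate(b[8] + 0.1, ser, par)
  expect_true(hi$censored_high)
  expect_equal(hi$lower_ug, 2.4)
  lo <- bracket_estimate(b[1] - 0.1, ser, par)
  expect_true(lo$censored_low)
  expect_equal(lo$upper_ug, 1.0)
  # a non-monotone series is an unusable replicate
  bad <- reference_series(a, rev(b))
  expect_false(bad$monotonic)
  expect_error(bracket_estimate(0.4, bad, par), "unusable")
})

test_that("bracketing agrees with a brute-force all-pairs oracle", {
  par <- fading_params()
  tol <- par$tie_tolerance * (1 - 1e-6)
  oracle_lower <- function(t, a, b) {
    if (t - b[length(b)] >= tol) return(c(a[length(a)], Inf))
    sim <- which(b - t < tol)
    if (!length(sim)) return(c(0, a[1]))
    i <- max(sim)
    if (i == length(a)) c(a[i], a[i]) else c(a[i], a[i + 1])
  }
  set.seed(42)
  a <- seq(1.0, 2.4, 0.2)
  for (rep in 1:300) {
    b <- sort(round(runif(8, 0.2, 0.8), 3))
    t <- runif(1, 0.1, 0.95)
    got <- bracket_estimate(t, reference_series(a, b), par)
    expect_identical(c(got$lower_ug, got$upper_ug), oracle_lower(t, a, b))
  }
})

test_that("percent conversion is the exact linear map of the worked scheme", {
  # 2 uL test spot: [1.4, 1.6] ug on a 200 mg claim is 70-80%, 140-160 mg
  est <- interval_to_percent(bracket(1.4, 1.6), 200)
  expect_equal(est$lower_pct, 70)
  expect_equal(est$upper_pct, 80)
  expect_equal(est$lower_mg, 140)
  expect_equal(est$upper_mg, 160)
  expect_equal(est$midpoint_pct, 75)
  # identity point and a larger claim
  expect_equal(interval_to_percent(bracket(2, 2), 200)$midpoint_pct, 100)
  e2 <- interval_to_percent(bracket(1.8, 2.0), 480)
  expect_equal(c(e2$lower_pct, e2$upper_pct), c(90, 100))
  expect_equal(c(e2$lower_mg, e2$upper_mg), c(432, 480))
  # exact up to floating representation across the binary-awkward 0.2 grid
  for (lo in seq(1.0, 2.4, 0.2)) {
    e <- interval_to_percent(bracket(lo, lo), 100)
    expect_lt(abs(e$lower_pct * 2 - lo * 100), 1e-12)
  }
  # censored ends propagate as open one-sided labels
  expect_equal(interval_to_percent(bracket(0, 1, "low"), 200)$label, "<50.0%")
  expect_equal(interval_to_percent(bracket(2.4, Inf, "high"), 200)$label,
               ">120.0%")
  expect_error(interval_to_percent(bracket(1, 2), 0), "claim")
})

test_that("replicate aggregation: moments, per-system means, censoring", {
  mk <- function(mid, sys, cens = "none")
    list(midpoint_pct = mid, censored = cens, solvent_system_id = sys)
  twelve <- lapply(1:12, function(i) mk(100, (i - 1) %/% 6 + 1))
  s <- aggregate_replicates(twelve)
  expect_equal(c(s$n, s$mean_pct, s$sd_pct), c(12, 100, 0))
  s3 <- aggregate_replicates(list(mk(98, 1), mk(100, 1), mk(102, 2)))
  expect_equal(s3$mean_pct, 100)
  expect_equal(s3$sd_pct, 2)
  expect_equal(unname(s3$system_means), c(99, 102))
  # permutation invariance and agreement with a streaming (Welford) oracle
  set.seed(1)
  vals <- runif(12, 80, 120)
  ests <- lapply(seq_along(vals), function(i) mk(vals[i], (i %% 2) + 1))
  s_a <- aggregate_replicates(ests)
  s_b <- aggregate_replicates(sample(ests))
  expect_equal(s_a$mean_pct, s_b$mean_pct, tolerance = 1e-12)
  expect_equal(s_a$sd_pct, s_b$sd_pct, tolerance = 1e-12)
  m <- 0; m2 <- 0
  for (k in seq_along(vals)) {
    d <- vals[k] - m; m <- m + d / k; m2 <- m2 + d * (vals[k] - m)
  }
  expect_equal(s_a$mean_pct, m, tolerance = 1e-9)
  expect_equal(s_a$sd_pct, sqrt(m2 / (length(vals) - 1)), tolerance = 1e-9)
  # censored replicates are counted, excluded from moments
  s_c <- aggregate_replicates(c(ests, list(mk(NA, 1, "high"))))
  expect_equal(s_c$censored_n, 1)
  expect_equal(s_c$mean_pct, s_a$mean_pct)
  all_c <- aggregate_replicates(list(mk(NA, 1, "high"), mk(NA, 2, "high")))
  expect_equal(all_c$censored, "high")
  expect_true(is.na(all_c$mean_pct))
  expect_error(aggregate_replicates(list()), "no replicate")
})

test_that("end-to-end plate quantification brackets the true content", {
  p <- generate_plate(content_spec(75, seed = 21))
  est <- quantify_plate(p, 200)
  expect_equal(est$censored, "none")
  expect_lte(est$lower_pct, 75)
  expect_gte(est$upper_pct, 75)
  expect_equal(est$upper_mg - est$lower_mg, 20)  # one 10% step of 200 mg
})

test_that("a blank test lane is censored low, gross overdose censored high", {
  blank <- generate_plate(content_spec(0, seed = 5))
  est <- quantify_plate(blank, 200)
  expect_equal(est$censored, "low")
  expect_match(est$flags, "no spot detected")
  expect_equal(est$label, "<50.0%")
  over <- generate_plate(content_spec(130, noise_sd = 0, seed = 5))
  est2 <- quantify_plate(over, 200)
  expect_equal(est2$censored, "high")
  expect_equal(est2$label, ">120.0%")
})
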