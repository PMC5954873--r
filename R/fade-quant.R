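#' Parameters of the brightness-sweep fading operator
#'
#' @param visibility_epsilon contrast below which a spot counts as invisible
#'   (default 0.02).
#' @param brightness_step sweep increment (default 1/255, one 8-bit level).
#' @param max_offset sweep cap (default 1, i.e. up to pure white).
#' @param tie_tolerance absolute difference in disappearance thresholds
#'   treated as "fading at the same time" (default one brightness step).
#' @param mode judge visibility on the `"peak"` contrast over the spot region
#'   (default: a spot is visible while any part of it is) or on the
#'   `"integrated"` (mean) contrast.
#' @return An object of class `fading_params`.
#' @export
fading_params <- function(visibility_epsilon = 0.02,
                          brightness_step = 1 / 255,
                          max_offset = 1,
                          tie_tolerance = brightness_step,
                          mode = c("peak", "integrated")) {
  stopifnot(visibility_epsilon > 0, visibility_epsilon < 1,
            brightness_step > 0, brightness_step <= max_offset,
            tie_tolerance >= 0)
  structure(list(visibility_epsilon = visibility_epsilon,
                 brightness_step = brightness_step,
                 max_offset = max_offset,
                 tie_tolerance = tie_tolerance,
                 mode = match.arg(mode)),
            class = "fading_params")
}

#' Brighten an image by an additive offset
#'
#' The mechanised counterpart of an office image tool's brightness slider:
#' every pixel is mapped to `min(pixel + offset, 1)`.  Order-preserving and
#' the identity at offset 0.
#'
#' @param img numeric matrix/vector in `[0, 1]`, or an `sqtlc_plate`.
#' @param offset nonnegative brightness offset.
#' @return The brightened object, same type as the input.
#' @export
brighten <- function(img, offset) {
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  if (inherits(img, "sqtlc_plate")) {
    img$pixels <- pmin(img$pixels + offset, 1)
    return(img)
  }
  pmin(img + offset, 1)
}

#' Disappearance threshold of a spot under the brightness sweep
#'
#' Sweeps the brightness offset from 0 to `max_offset` in steps of
#' `brightness_step`, brightening the image and background together, and
#' records the contrast of the spot region (background minus pixel, after
#' both are clipped at white) at every step.  The disappearance threshold
#' `b_star` is the smallest offset at which the region's contrast drops below
#' `visibility_epsilon`; if that never happens the profile is censored at
#' `max_offset`.
#'
#' @param plate an `sqtlc_plate` or pixel matrix.
#' @param background background matrix (same shape).
#' @param region integer vector of linear pixel indices of the spot region.
#' @param params a [fading_params()].
#' @param lane optional lane index carried into the profile.
#' @return An object of class `fading_profile`: `lane`, `offsets`,
#'   `contrast` (the audit curve), `b_star`, `censored`.
#' @export
fading_threshold <- function(plate, background, region,
                             params = fading_params(), lane = NA_integer_) {
  if (length(region) == 0) stop("empty spot region", call. = FALSE)
  px <- if (is.matrix(plate)) plate else plate$pixels
  p <- px[region]; b <- background[region]
  offsets <- seq(0, params$max_offset, by = params$brightness_step)
  # contrast at offset o: reduce over region of min(b+o,1) - min(p+o,1)
  pm <- pmin(outer(p, offsets, `+`), 1)
  bm <- pmin(outer(b, offsets, `+`), 1)
  cm <- bm - pm
  curve <- if (params$mode == "peak") apply(cm, 2, max) else colMeans(cm)
  hit <- which(curve < params$visibility_epsilon)
  censored <- length(hit) == 0
  b_star <- if (censored) params$max_offset else offsets[hit[1]]
  # sub-step refinement: linear interpolation of the visibility crossing.
  # The grid b_star quantizes the crossing up to a full sweep step; for
  # comparing lanes against each other the interpolated crossing restores
  # the resolution a continuous visual comparison has.
  b_star_refined <- if (censored) params$max_offset
  else if (hit[1] == 1) 0
  else {
    j <- hit[1]
    c1 <- curve[j - 1]; c2 <- curve[j]
    offsets[j - 1] + (c1 - params$visibility_epsilon) /
      max(c1 - c2, .Machine$double.eps) * params$brightness_step
  }
  structure(list(lane = lane, offsets = offsets, contrast = curve,
                 b_star = b_star, b_star_refined = b_star_refined,
                 censored = censored),
            class = "fading_profile")
}

#' @export
print.fading_profile <- function(x, ...) {
  cat(sprintf("Fading profile (lane %s): b* = %.4f%s\n", format(x$lane),
              x$b_star, if (x$censored) " (censored at sweep cap)" else ""))
  invisible(x)
}

#' Reference series of disappearance thresholds
#'
#' The assay's ruler: the graded reference-standard amounts together with the
#' disappearance threshold measured for each RS lane.  A valid series has
#' thresholds nondecreasing in amount (more substance survives brightening
#' longer); violations are flagged and make the replicate unusable for
#' bracketing.
#'
#' Thresholds are required to be nondecreasing in amount up to a
#' discretisation tolerance: an inversion no larger than `tolerance`
#' (default one brightness step, matching the tie rule of
#' [fading_params()]) counts as simultaneous fading, not a violation.
#'
#' @param amounts_ug strictly increasing RS amounts (ug).
#' @param b_stars disappearance thresholds, one per amount.
#' @param tolerance largest inversion still treated as a tie.
#' @return An object of class `reference_series` with a `monotonic` flag.
#' @export
reference_series <- function(amounts_ug, b_stars, tolerance = 1 / 255) {
  stopifnot(length(amounts_ug) == length(b_stars), length(amounts_ug) >= 2)
  if (is.unsorted(amounts_ug, strictly = TRUE))
    stop("RS amounts must be strictly increasing", call. = FALSE)
  structure(list(amounts_ug = amounts_ug, b_stars = b_stars,
                 monotonic = all(diff(b_stars) >= -tolerance)),
            class = "reference_series")
}

#' Bracket a test spot within the reference series
#'
#' Locates the test spot's disappearance threshold among those of the RS
#' series.  Two thresholds closer than `tie_tolerance` are indistinguishable
#' on the sweep grid and count as "fading at the same time".
#'
#' Under the default rule (`tie_rule = "lower"`, the assay's reading
#' procedure) the lower limit is the largest RS amount that fades
#' simultaneously with or before the test spot, and the upper limit is the
#' next RS amount up — the one that fades completely after the test — so the
#' reported estimate is always a genuine interval `[a_i, a_(i+1)]`.  With
#' `tie_rule = "point"` a simultaneous fade instead yields the degenerate
#' bracket `[a_i, a_i]` (a point estimate at the matching RS amount).
#'
#' A test spot fading a full tolerance before the smallest RS spot is
#' censored low (only "< smallest amount" is supported); one outlasting the
#' largest RS spot by more than the tolerance is censored high.
#'
#' @param test_b_star disappearance threshold of the test spot.
#' @param series a [reference_series()]; must be monotonic.
#' @param params a [fading_params()] (supplies `tie_tolerance`).
#' @param tie_rule `"lower"` (default) or `"point"`, see Details.
#' @param replicate_id,solvent_system_id metadata carried through.
#' @return An object of class `bracket_estimate`: `lower_ug`, `upper_ug`,
#'   `censored_low`, `censored_high`, `test_volume_ul` (fixed 2.0),
#'   plus the metadata.
#' @export
bracket_estimate <- function(test_b_star, series, params = fading_params(),
                             tie_rule = c("lower", "point"),
                             replicate_id = NA, solvent_system_id = NA) {
  stopifnot(inherits(series, "reference_series"))
  tie_rule <- match.arg(tie_rule)
  if (!series$monotonic)
    stop("unusable replicate: reference-series fading thresholds are not ",
         "nondecreasing in amount", call. = FALSE)
  a <- series$amounts_ug; b <- series$b_stars
  n <- length(a)
  # thresholds are grid multiples; shave an ulp-scale margin off the
  # tolerance so strict comparisons do not flip on representation error
  tol <- params$tie_tolerance * (1 - 1e-6)
  mk <- function(lo, hi, clo = FALSE, chi = FALSE) {
    structure(list(lower_ug = lo, upper_ug = hi, censored_low = clo,
                   censored_high = chi, test_volume_ul = 2.0,
                   replicate_id = replicate_id,
                   solvent_system_id = solvent_system_id),
              class = "bracket_estimate")
  }
  if (tie_rule == "point") {
    d <- abs(b - test_b_star)
    if (any(d < tol)) return(mk(a[which.min(d)], a[which.min(d)]))
    if (test_b_star < b[1]) return(mk(0, a[1], clo = TRUE))
    if (test_b_star > b[n]) return(mk(a[n], Inf, chi = TRUE))
    i <- max(which(b < test_b_star))
    return(mk(a[i], a[i + 1]))
  }
  # "lower": largest RS fading simultaneously with or before the test spot
  if (test_b_star - b[n] >= tol) return(mk(a[n], Inf, chi = TRUE))
  sim_or_before <- which(b - test_b_star < tol)
  if (!length(sim_or_before)) return(mk(0, a[1], clo = TRUE))
  i <- max(sim_or_before)
  if (i == n) return(mk(a[n], a[n]))
  mk(a[i], a[i + 1])
}

#' Construct a bracket estimate directly
#'
#' Convenience constructor for a bracket already known in micrograms (e.g.
#' when transcribing a worked determination), bypassing the fading sweep.
#'
#' @param lower_ug,upper_ug bracketing amounts in micrograms.
#' @param censored `"none"`, `"low"` or `"high"`.
#' @param replicate_id,solvent_system_id metadata carried through.
#' @return An object of class `bracket_estimate`.
#' @export
bracket <- function(lower_ug, upper_ug, censored = "none",
                    replicate_id = NA, solvent_system_id = NA) {
  censored <- match.arg(censored, c("none", "low", "high"))
  if (censored == "high" && !is.finite(upper_ug)) upper_ug <- Inf
  stopifnot(lower_ug <= upper_ug)
  structure(list(lower_ug = lower_ug, upper_ug = upper_ug,
                 censored_low = censored == "low",
                 censored_high = censored == "high",
                 test_volume_ul = 2.0, replicate_id = replicate_id,
                 solvent_system_id = solvent_system_id),
            class = "bracket_estimate")
}

#' @export
print.bracket_estimate <- function(x, ...) {
  lab <- if (x$censored_low) sprintf("< %.1f ug", x$upper_ug)
  else if (x$censored_high) sprintf("> %.1f ug", x$lower_ug)
  else sprintf("[%.1f, %.1f] ug", x$lower_ug, x$upper_ug)
  cat("Bracket estimate:", lab, "(2.0 uL test spot)\n")
  invisible(x)
}

#' Convert a bracket to percent of label claim and mass
#'
#' With a fixed 2.0 uL test spot of a 1 mg/mL solution, an RS amount of
#' `a` ug corresponds to `a / 2.0 * 100` percent of the label claim, and to
#' `pct / 100 * claim_mg` milligrams of API.  Censored bracket ends propagate
#' as open bounds: a spot fading before the 1.0 ug RS spot supports only
#' "< 50 %", one outlasting the 2.4 ug spot only "> 120 %".
#'
#' @param bracket a [bracket_estimate()].
#' @param claim_mg label claim in mg (> 0).
#' @return An object of class `percent_estimate`: `lower_pct`, `upper_pct`,
#'   `midpoint_pct` (NA when censored), `lower_mg`, `upper_mg`, `censored`
#'   (`"none"`, `"low"`, `"high"`), `label`, plus replicate metadata.
#' @export
interval_to_percent <- function(bracket, claim_mg) {
  if (!is.finite(claim_mg) || claim_mg <= 0)
    stop("claim_mg must be > 0", call. = FALSE)
  vol <- bracket$test_volume_ul
  lower_pct <- bracket$lower_ug / vol * 100
  upper_pct <- if (is.finite(bracket$upper_ug))
    bracket$upper_ug / vol * 100 else Inf
  censored <- if (bracket$censored_low) "low"
  else if (bracket$censored_high) "high" else "none"
  mid <- if (censored == "none") (lower_pct + upper_pct) / 2 else NA_real_
  label <- switch(censored,
    none = sprintf("%.1f–%.1f%%", lower_pct, upper_pct),
    low = sprintf("<%.1f%%", upper_pct),
    high = sprintf(">%.1f%%", lower_pct))
  structure(list(lower_pct = lower_pct, upper_pct = upper_pct,
                 midpoint_pct = mid,
                 lower_mg = lower_pct / 100 * claim_mg,
                 upper_mg = upper_pct / 100 * claim_mg,
                 claim_mg = claim_mg, censored = censored, label = label,
                 replicate_id = bracket$replicate_id,
                 solvent_system_id = bracket$solvent_system_id),
            class = "percent_estimate")
}

#' @export
print.percent_estimate <- function(x, ...) {
  cat(sprintf("API content: %s of label claim", x$label))
  if (x$censored == "none")
    cat(sprintf(" (%.4g–%.4g mg of %.4g mg claimed)",
                x$lower_mg, x$upper_mg, x$claim_mg))
  cat("\n")
  invisible(x)
}

#' Aggregate replicate percent estimates
#'
#' Pools the replicate midpoints of a 12-fold determination (6 per solvent
#' system): mean, sample standard deviation (n - 1), per-solvent-system
#' means, and the count of censored replicates (excluded from the moments).
#' If every replicate is censored the summary is itself censored, in the
#' majority direction.
#'
#' @param estimates list of [interval_to_percent()] results (each carrying
#'   `solvent_system_id`), or a data frame with columns `midpoint_pct`,
#'   `censored`, `solvent_system_id`.
#' @return An object of class `replicate_summary`: `n`, `mean_pct`, `sd_pct`,
#'   `system_means` (named), `censored_n`, `censored` direction.
#' @export
aggregate_replicates <- function(estimates) {
  df <- if (is.data.frame(estimates)) estimates else do.call(rbind, lapply(
    estimates, function(e) data.frame(
      midpoint_pct = e$midpoint_pct, censored = e$censored,
      solvent_system_id = e$solvent_system_id,
      stringsAsFactors = FALSE)))
  if (is.null(df) || nrow(df) == 0) stop("no replicate estimates",
                                         call. = FALSE)
  ok <- df$censored == "none"
  censored_n <- sum(!ok)
  if (!any(ok)) {
    dir <- names(sort(table(df$censored[!ok]), decreasing = TRUE))[1]
    return(structure(list(n = nrow(df), mean_pct = NA_real_,
                          sd_pct = NA_real_, system_means = NULL,
                          censored_n = censored_n, censored = dir),
                     class = "replicate_summary"))
  }
  mids <- df$midpoint_pct[ok]
  sys <- df$solvent_system_id[ok]
  system_means <- tapply(mids, sys, mean)
  system_means <- stats::setNames(as.numeric(system_means),
                                  names(system_means))
  structure(list(n = nrow(df), mean_pct = mean(mids),
                 sd_pct = if (length(mids) > 1) stats::sd(mids) else 0,
                 system_means = system_means,
                 censored_n = censored_n, censored = "none"),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  if (x$censored != "none") {
    cat(sprintf("Replicate summary: all %d replicate(s) censored (%s)\n",
                x$n, x$censored))
  } else {
    cat(sprintf("Replicate summary (n = %d): %.1f ± %.1f %% of claim",
                x$n, x$mean_pct, x$sd_pct))
    if (x$censored_n > 0) cat(sprintf(" [%d censored]", x$censored_n))
    cat("\n")
    if (!is.null(x$system_means))
      cat("  per-system means:",
          paste(sprintf("S%s %.1f", names(x$system_means), x$system_means),
                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Quantify one plate end to end
#'
#' Composes the full single-plate pipeline: background estimation, spot
#' detection, lane assignment, a fading sweep per lane, bracketing of the
#' test spot within the RS series, and conversion to percent of label claim.
#' The audit trail (detections, per-lane fading profiles, the bracket) is
#' attached to the result.
#'
#' Before the sweep the plate is flat-field corrected: the estimated
#' background is divided out additively, leaving every spot's darkness
#' deficit on a uniform white field.  Without this step a background
#' gradient biases the comparison — a spot sitting on a brighter part of the
#' plate clips to white sooner under the additive sweep and appears to hold
#' less substance than an equally dark spot elsewhere.
#'
#' @param plate an `sqtlc_plate`.
#' @param claim_mg label claim of the assayed API in mg.
#' @param params a [fading_params()].
#' @param min_area,contrast_floor detection parameters, see [detect_spots()].
#' @param denoise_sigma Gaussian smoothing (px) applied to the flattened
#'   image before the sweep; 0 disables.
#' @param tie_rule bracketing rule, see [bracket_estimate()].
#' @return A [interval_to_percent()] result with an `audit` field; a plate
#'   whose test lane holds no detectable spot yields a censored-low estimate
#'   flagged `"no spot detected"`; a plate with a missing or non-monotone RS
#'   series throws an error (unusable replicate).
#' @export
quantify_plate <- function(plate, claim_mg, params = fading_params(),
                           min_area = 20L, contrast_floor = 0.05,
                           denoise_sigma = 2.5,
                           tie_rule = c("lower", "point")) {
  tie_rule <- match.arg(tie_rule)
  layout <- plate$layout
  bg <- estimate_background(plate)
  det <- detect_spots(plate, min_area = min_area,
                      contrast_floor = contrast_floor, background = bg)
  det <- assign_lanes(det, layout)
  n_lane <- length(layout$application_xs)
  rs_lanes <- setdiff(seq_len(n_lane), layout$test_lane_index)
  # flat-field correction: deficits on a uniform white background; light
  # smoothing emulates the spatial averaging of visual inspection and is a
  # lane-uniform rescaling, so the ordinal comparison is untouched
  flat <- pmin(pmax(1 - (bg - plate$pixels), 0), 1)
  if (denoise_sigma > 0) flat <- gaussian_blur(flat, denoise_sigma)
  white <- matrix(1, nrow(flat), ncol(flat))
  profiles <- vector("list", n_lane)
  b_stars <- rep(NA_real_, n_lane)
  for (lane in seq_len(n_lane)) {
    i <- which(det$lane == lane & det$primary)
    if (length(i) != 1) next
    profiles[[lane]] <- fading_threshold(flat, white, det$region[[i]],
                                         params, lane = lane)
    b_stars[lane] <- profiles[[lane]]$b_star_refined
  }
  # lanes are compared on the interpolated crossings, which carry no grid
  # quantization; simultaneity then means numerically indistinguishable
  cmp_params <- params
  cmp_params$tie_tolerance <- 1e-9
  if (anyNA(b_stars[rs_lanes]))
    stop("unusable replicate: reference-standard lane(s) ",
         paste(rs_lanes[is.na(b_stars[rs_lanes])], collapse = ", "),
         " have no detected spot", call. = FALSE)
  series <- reference_series(layout$rs_amounts_ug, b_stars[rs_lanes])
  meta <- plate$meta
  rid <- if (!is.null(meta)) meta$replicate else NA
  test_b <- b_stars[layout$test_lane_index]
  if (is.na(test_b)) {
    bracket <- structure(list(lower_ug = 0,
                              upper_ug = layout$rs_amounts_ug[1],
                              censored_low = TRUE, censored_high = FALSE,
                              test_volume_ul = 2.0, replicate_id = rid,
                              solvent_system_id = plate$solvent_system_id),
                         class = "bracket_estimate")
    est <- interval_to_percent(bracket, claim_mg)
    est$flags <- "no spot detected"
  } else {
    bracket <- bracket_estimate(test_b, series, cmp_params,
                                tie_rule = tie_rule, replicate_id = rid,
                                solvent_system_id = plate$solvent_system_id)
    est <- interval_to_percent(bracket, claim_mg)
    est$flags <- ""
  }
  est$audit <- list(detections = det, profiles = profiles, series = series,
                    bracket = bracket, background_low_confidence =
                      isTRUE(attr(bg, "low_confidence")))
  est
}
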