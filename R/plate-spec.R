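#' Specification of a synthetic TLC plate
#'
#' A `plate_spec` bundles the geometry, chemistry stand-ins and noise model
#' used by [generate_plate()].  Lanes run vertically; spots are applied on the
#' origin row and migrate upward toward the solvent front (row indices are
#' 1-based and counted from the top of the image, so `front_y < origin_y`).
#' The last lane is the test spot; all preceding lanes form the graded
#' reference-standard (RS) series.  Amounts are in micrograms; because the RS
#' is spotted as 1 mg/mL, volume in microlitres and mass in micrograms
#' coincide.
#'
#' The peak darkness of a spot of amount `a` follows a saturating-linear
#' response: `d0 + k * a` on `[0, saturation_knee]`, then a compressed tail of
#' slope `k / 8` beyond the knee.  The linear segment covers the assay's
#' working range (1.0--2.0 ug/spot); the shallow tail keeps darkness strictly
#' increasing so the largest RS spot remains the last to fade.
#'
#' @param width_px,height_px image size in pixels.
#' @param origin_y,front_y application-line and solvent-front rows (1-based,
#'   from the top; `front_y < origin_y`).
#' @param application_xs strictly increasing lane columns, RS series first,
#'   test lane last.
#' @param rf_per_lane migration fraction in `[0, 1]` per lane (recycled).
#' @param amounts_ug spotted amount per lane in micrograms; RS amounts must be
#'   strictly increasing.  A zero amount produces no spot (blank lane).
#' @param spot_sigma_px Gaussian spot radius (standard deviation) in pixels.
#' @param background_level base background gray in `[0, 1]` (1 = white).
#' @param background_tilt maximum background gradient across the plate width.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param darkness_intercept,darkness_slope intercept `d0` and slope `k` of
#'   the amount-to-peak-darkness response.
#' @param saturation_knee amount (ug) beyond which the response flattens to
#'   slope `k / 8`.
#' @param seed integer seed making the generated plate reproducible.
#' @return An object of class `plate_spec`.
#' @seealso [generate_plate()], [lane_layout()]
#' @export
plate_spec <- function(width_px = 400L, height_px = 200L,
                       origin_y = 170L, front_y = 30L,
                       application_xs = seq(40L, 360L, by = 40L),
                       rf_per_lane = 0.45,
                       amounts_ug = c(seq(1.0, 2.4, by = 0.2), 2.0),
                       spot_sigma_px = 6,
                       background_level = 0.9,
                       background_tilt = 0.05,
                       noise_sd = 0.01,
                       darkness_intercept = 0.10,
                       darkness_slope = 0.25,
                       saturation_knee = 2.4,
                       seed = 1L) {
  n_lane <- length(application_xs)
  spec <- structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    origin_y = as.integer(origin_y), front_y = as.integer(front_y),
    application_xs = as.integer(application_xs),
    rf_per_lane = rep_len(rf_per_lane, n_lane),
    amounts_ug = amounts_ug,
    spot_sigma_px = spot_sigma_px,
    background_level = background_level,
    background_tilt = background_tilt,
    noise_sd = noise_sd,
    darkness_intercept = darkness_intercept,
    darkness_slope = darkness_slope,
    saturation_knee = saturation_knee,
    seed = as.integer(seed)
  ), class = "plate_spec")
  validate_plate_spec(spec)
  spec
}

validate_plate_spec <- function(spec) {
  with(spec, {
    if (!(1 <= front_y && front_y < origin_y && origin_y <= height_px))
      stop("invalid plate geometry: need 1 <= front_y < origin_y <= height_px",
           call. = FALSE)
    if (any(application_xs < 1) || any(application_xs > width_px))
      stop("application_xs out of raster bounds", call. = FALSE)
    if (is.unsorted(application_xs, strictly = TRUE))
      stop("application_xs must be strictly increasing", call. = FALSE)
    if (length(amounts_ug) != length(application_xs))
      stop("amounts_ug must have one entry per lane", call. = FALSE)
    if (any(rf_per_lane < 0 | rf_per_lane > 1))
      stop("rf_per_lane must lie in [0, 1]", call. = FALSE)
    if (any(amounts_ug < 0)) stop("amounts_ug must be >= 0", call. = FALSE)
    if (background_level + abs(background_tilt) > 1)
      stop("background_level + |background_tilt| must be <= 1", call. = FALSE)
    rs <- amounts_ug[-length(amounts_ug)]
    rs <- rs[rs > 0]  # zero = unspotted lane (blank plates are legal)
    if (length(rs) >= 2 && is.unsorted(rs, strictly = TRUE))
      stop("reference-series amounts must be strictly increasing",
           call. = FALSE)
    if (length(application_xs) >= 2 &&
        min(diff(application_xs)) < 4 * spot_sigma_px)
      stop("layout error: inter-lane spacing below 4 * spot_sigma_px; ",
           "lanes would overlap", call. = FALSE)
  })
  invisible(spec)
}

#' Lane layout metadata for a plate image
#'
#' The layout sidecar an analyst would record for a scanned plate: where the
#' application origin and the solvent front are, where the lanes were spotted,
#' and which amounts the reference-standard (RS) lanes carry.
#'
#' @param origin_y,front_y application-line and solvent-front rows (1-based
#'   from the top; `front_y < origin_y`).
#' @param application_xs strictly increasing lane columns.
#' @param lane_half_width half-width (px) within which a detection is
#'   attributed to a lane.
#' @param rs_amounts_ug strictly increasing RS amounts (ug), one per RS lane.
#' @param test_lane_index index of the test lane among `application_xs`
#'   (default: the last lane).
#' @return An object of class `lane_layout`.
#' @export
lane_layout <- function(origin_y, front_y, application_xs,
                        lane_half_width = 15,
                        rs_amounts_ug = seq(1.0, 2.4, by = 0.2),
                        test_lane_index = length(application_xs)) {
  layout <- structure(list(
    origin_y = as.integer(origin_y), front_y = as.integer(front_y),
    application_xs = as.integer(application_xs),
    lane_half_width = lane_half_width,
    rs_amounts_ug = rs_amounts_ug,
    test_lane_index = as.integer(test_lane_index)
  ), class = "lane_layout")
  validate_lane_layout(layout)
  layout
}

validate_lane_layout <- function(layout) {
  with(layout, {
    if (front_y >= origin_y)
      stop("layout requires front_y < origin_y (rows counted from the top)",
           call. = FALSE)
    if (is.unsorted(application_xs, strictly = TRUE))
      stop("application_xs must be strictly increasing", call. = FALSE)
    if (any(rs_amounts_ug > 0) &&
        is.unsorted(rs_amounts_ug, strictly = TRUE))
      stop("rs_amounts_ug must be strictly increasing", call. = FALSE)
    if (test_lane_index < 1 || test_lane_index > length(application_xs))
      stop("test_lane_index out of range", call. = FALSE)
    if (length(rs_amounts_ug) != length(application_xs) - 1)
      stop("rs_amounts_ug must cover every lane except the test lane",
           call. = FALSE)
  })
  invisible(layout)
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf("TLC plate spec: %d x %d px, %d lanes (test lane last)\n",
              x$width_px, x$height_px, length(x$application_xs)))
  cat(sprintf("  origin row %d, front row %d; amounts (ug): %s\n",
              x$origin_y, x$front_y,
              paste(format(x$amounts_ug), collapse = ", ")))
  cat(sprintf("  background %.2f (tilt %.2f), noise sd %.3f, seed %d\n",
              x$background_level, x$background_tilt, x$noise_sd, x$seed))
  invisible(x)
}

# layout implied by a generator spec (single source of truth for tests)
layout_from_spec <- function(spec) {
  n <- length(spec$application_xs)
  half <- if (n >= 2) min(diff(spec$application_xs)) / 2 else
    4 * spec$spot_sigma_px
  lane_layout(spec$origin_y, spec$front_y, spec$application_xs,
              lane_half_width = half,
              rs_amounts_ug = spec$amounts_ug[-n],
              test_lane_index = n)
}
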