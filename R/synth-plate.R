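#' Peak darkness of a spot as a function of spotted amount
#'
#' Saturating-linear response used by the generator: linear
#' `d0 + k * a` up to the saturation knee, then a compressed tail of slope
#' `k / 8`, clamped to `[0, 1]`.  Strictly increasing in the amount whenever
#' `k > 0`, so a larger spotted amount always survives a brightness sweep
#' longer.
#'
#' @param amount_ug spotted amount(s), micrograms.
#' @param spec a [plate_spec()] supplying `darkness_intercept`,
#'   `darkness_slope` and `saturation_knee`.
#' @return Peak darkness value(s) in `[0, 1]`.
#' @export
peak_darkness <- function(amount_ug, spec) {
  d <- spec$darkness_intercept +
    spec$darkness_slope * pmin(amount_ug, spec$saturation_knee) +
    (spec$darkness_slope / 8) * pmax(amount_ug - spec$saturation_knee, 0)
  pmin(pmax(d, 0), 1)
}

background_field <- function(spec) {
  ramp <- if (spec$width_px > 1)
    (seq_len(spec$width_px) - 1) / (spec$width_px - 1) - 0.5 else 0
  bg <- matrix(spec$background_level + spec$background_tilt * ramp,
               nrow = spec$height_px, ncol = spec$width_px, byrow = TRUE)
  pmin(pmax(bg, 0), 1)
}

#' Generate a synthetic TLC plate with exact ground truth
#'
#' Renders a grayscale plate (0 = black, 1 = white): a light, mildly tilted
#' background minus one Gaussian darkness deficit per spotted lane, plus
#' additive Gaussian noise, clamped to `[0, 1]`.  Spot centres sit at each
#' lane's column, at the row implied by its retention factor
#' (`origin_y - rf * (origin_y - front_y)`, rounded to a pixel).  Deterministic
#' for a fixed `spec$seed`.
#'
#' @param spec a [plate_spec()].
#' @param solvent_system_id identifier carried through to the plate metadata.
#' @return A list of class `sqtlc_plate` with elements `pixels` (matrix,
#'   rows = image rows), `layout` (a [lane_layout()]), `truth` (data frame of
#'   per-spot ground truth: `lane`, `cx`, `cy`, `amount_ug`, `peak_darkness`,
#'   `rf`; one row per nonzero amount), `spec`, `provenance` and
#'   `solvent_system_id`.
#' @examples
#' p <- generate_plate(plate_spec(noise_sd = 0))
#' range(p$pixels)
#' p$truth
#' @export
generate_plate <- function(spec, solvent_system_id = 1L) {
  validate_plate_spec(spec)
  set.seed(spec$seed)
  img <- background_field(spec)
  h <- spec$height_px; w <- spec$width_px
  mig <- spec$origin_y - spec$front_y
  truth <- list()
  for (i in seq_along(spec$application_xs)) {
    a <- spec$amounts_ug[i]
    if (a <= 0) next
    cx <- spec$application_xs[i]
    cy <- as.integer(round(spec$origin_y - spec$rf_per_lane[i] * mig))
    d <- peak_darkness(a, spec)
    gy <- exp(-((seq_len(h) - cy)^2) / (2 * spec$spot_sigma_px^2))
    gx <- exp(-((seq_len(w) - cx)^2) / (2 * spec$spot_sigma_px^2))
    img <- img - d * (gy %o% gx)
    truth[[length(truth) + 1L]] <- data.frame(
      lane = i, cx = cx, cy = cy, amount_ug = a, peak_darkness = d,
      rf = (spec$origin_y - cy) / mig)
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), nrow = h)
  img <- pmin(pmax(img, 0), 1)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(lane = integer(), cx = integer(), cy = integer(),
               amount_ug = numeric(), peak_darkness = numeric(),
               rf = numeric())
  structure(list(pixels = img, layout = layout_from_spec(spec),
                 truth = truth, spec = spec,
                 provenance = list(source = "generated", seed = spec$seed),
                 solvent_system_id = solvent_system_id),
            class = "sqtlc_plate")
}

#' @export
print.sqtlc_plate <- function(x, ...) {
  cat(sprintf("Synthetic TLC plate: %d x %d px, %d spot(s), system %s\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$truth),
              format(x$solvent_system_id)))
  invisible(x)
}

#' Generate a replicated assay campaign from a sample manifest
#'
#' For every assayable API of every sample in the manifest, generates 12
#' replicate plates: 6 in each of two solvent systems, each system with its
#' own retention factor.  The test-lane amount encodes the sample's true API
#' content: `true_pct / 100 * 2.0` ug (the fixed 2 uL test spot of a 1 mg/mL
#' solution).  Per-plate seeds are drawn reproducibly from `seed`.
#'
#' @param manifest data frame with one row per sample-API, as returned by
#'   [load_manifest()]; only columns `sample_code`, `api` and `claim_mg` are
#'   required.  Rows flagged non-assayable (`assayable == FALSE`) are skipped.
#' @param template a [plate_spec()] used for every plate; its `rf_per_lane`
#'   and test-lane amount are overridden per replicate.
#' @param seed master seed for the campaign.
#' @param true_pct true content as percent of label claim: a single number,
#'   or a named vector keyed by `"<sample_code>:<api>"`.  Default 100.
#' @param replicates_per_system replicates per solvent system (default 6).
#' @param rf_systems retention factors for the two solvent systems.
#' @return A list of class `sqtlc_campaign`: element `plates` is a list of
#'   `sqtlc_plate` objects, each with a `meta` field (`sample_code`, `api`,
#'   `claim_mg`, `true_pct`, `solvent_system_id`, `replicate`); element
#'   `manifest` echoes the input.
#' @export
generate_campaign <- function(manifest, template = plate_spec(), seed = 1L,
                              true_pct = 100, replicates_per_system = 6L,
                              rf_systems = c(0.45, 0.60)) {
  stopifnot(is.data.frame(manifest))
  if (!all(c("sample_code", "api", "claim_mg") %in% names(manifest)))
    stop("manifest needs columns sample_code, api, claim_mg", call. = FALSE)
  if ("assayable" %in% names(manifest))
    manifest <- manifest[manifest$assayable, , drop = FALSE]
  plates <- list()
  if (nrow(manifest) == 0)
    return(structure(list(plates = plates, manifest = manifest, seed = seed),
                     class = "sqtlc_campaign"))
  set.seed(seed)
  n_lane <- length(template$application_xs)
  n_plates <- nrow(manifest) * 2L * replicates_per_system
  plate_seeds <- sample.int(.Machine$integer.max - 1L, n_plates)
  k <- 0L
  for (r in seq_len(nrow(manifest))) {
    key <- paste0(manifest$sample_code[r], ":", manifest$api[r])
    pct <- if (length(true_pct) == 1 && is.null(names(true_pct)))
      true_pct else unname(true_pct[key])
    if (is.na(pct))
      stop("no true_pct entry for ", key, call. = FALSE)
    for (sys in 1:2) {
      for (rep_i in seq_len(replicates_per_system)) {
        k <- k + 1L
        spec <- template
        spec$rf_per_lane <- rep(rf_systems[sys], n_lane)
        spec$amounts_ug[n_lane] <- pct / 100 * 2.0
        spec$seed <- plate_seeds[k]
        plate <- generate_plate(spec, solvent_system_id = sys)
        plate$meta <- list(sample_code = manifest$sample_code[r],
                           api = manifest$api[r],
                           claim_mg = manifest$claim_mg[r],
                           true_pct = pct,
                           solvent_system_id = sys, replicate = rep_i)
        plates[[k]] <- plate
      }
    }
  }
  structure(list(plates = plates, manifest = manifest, seed = seed),
            class = "sqtlc_campaign")
}

#' @export
print.sqtlc_campaign <- function(x, ...) {
  cat(sprintf("SQ-TLC campaign: %d plates (%d sample-API pairs x 12)\n",
              length(x$plates), nrow(x$manifest)))
  invisible(x)
}
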