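#' Specificity via retention-factor agreement
#'
#' A test spot is identified as the claimed API when its retention factor
#' matches the reference standard's run under the same conditions.
#'
#' @param rf_test,rf_rs paired retention factors (vectorised).
#' @param tolerance maximum |difference| that still passes (default 0.05).
#' @return A data frame: `rf_test`, `rf_rs`, `delta_rf`, `pass`,
#'   `out_of_range` (flagging values outside `[0, 1]`).
#' @export
specificity_check <- function(rf_test, rf_rs, tolerance = 0.05) {
  stopifnot(length(rf_test) == length(rf_rs))
  delta <- abs(rf_test - rf_rs)
  data.frame(rf_test = rf_test, rf_rs = rf_rs, delta_rf = delta,
             pass = delta <= tolerance + 1e-9,
             out_of_range = rf_test < 0 | rf_test > 1 |
               rf_rs < 0 | rf_rs > 1)
}

#' Precision as relative standard deviation
#'
#' RSD = sd (n - 1 denominator) / mean x 100, computed within each solvent
#' system (n = 6 per system in the standard design) and averaged across
#' systems.
#'
#' @param values replicate percent estimates.
#' @param systems solvent-system id per value (default: one system).
#' @return A list: `per_system` (named RSD %), `mean_rsd` (their average),
#'   `n` per system.
#' @export
precision_rsd <- function(values, systems = rep(1L, length(values))) {
  stopifnot(length(values) == length(systems))
  per <- tapply(values, systems, function(v) {
    if (length(v) < 2) stop("need n >= 2 per solvent system", call. = FALSE)
    m <- mean(v)
    if (m == 0) stop("zero mean; RSD undefined", call. = FALSE)
    stats::sd(v) / m * 100
  })
  per <- stats::setNames(as.numeric(per), names(per))
  list(per_system = per, mean_rsd = mean(per),
       n = c(tapply(values, systems, length)))
}

#' Linearity of the fading signal over the working range
#'
#' Ordinary least squares of the fading signal (e.g. disappearance
#' thresholds) on spotted amount, restricted to the assay's declared linear
#' range; points outside the range are excluded and counted.
#'
#' @param amounts_ug spotted amounts (ug).
#' @param signal fading signal per amount.
#' @param range working range, default `c(1.0, 2.0)` ug.
#' @return A list: `slope`, `intercept`, `r` (Pearson), `n_used`,
#'   `n_excluded`, `fit` (the `lm` object).
#' @export
linearity_fit <- function(amounts_ug, signal, range = c(1.0, 2.0)) {
  stopifnot(length(amounts_ug) == length(signal))
  keep <- amounts_ug >= range[1] & amounts_ug <= range[2]
  a <- amounts_ug[keep]; s <- signal[keep]
  if (length(a) < 3)
    stop("need >= 3 points inside the linear range", call. = FALSE)
  if (stats::var(a) == 0)
    stop("zero variance in amounts; fit undefined", call. = FALSE)
  fit <- stats::lm(s ~ a)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(a, s), n_used = length(a),
       n_excluded = sum(!keep), fit = fit)
}

#' Accuracy against a reference method
#'
#' Summarises paired field (SQ-TLC) and reference (HPLC) percent values:
#' mean and sd of the field values, mean signed deviation from the
#' reference, and their Pearson correlation.
#'
#' @param tlc_pct,ref_pct paired percent-of-claim vectors (length >= 2).
#' @return A list: `mean_tlc`, `sd_tlc`, `mean_deviation`
#'   (mean of tlc - ref), `r`, `n`.
#' @export
accuracy_vs_reference <- function(tlc_pct, ref_pct) {
  if (length(tlc_pct) != length(ref_pct))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(tlc_pct) < 2) stop("need >= 2 pairs", call. = FALSE)
  r <- if (stats::var(tlc_pct) > 0 && stats::var(ref_pct) > 0)
    stats::cor(tlc_pct, ref_pct) else NA_real_
  list(mean_tlc = mean(tlc_pct), sd_tlc = stats::sd(tlc_pct),
       mean_deviation = mean(tlc_pct - ref_pct), r = r,
       n = length(tlc_pct))
}

#' Assemble an ICH-style validation report
#'
#' Bundles the four validation statistics into one JSON-serialisable report
#' (specificity, precision, linearity, accuracy), mirroring how a method
#' validation summary is reported.
#'
#' @param specificity output of [specificity_check()].
#' @param precision output of [precision_rsd()].
#' @param linearity output of [linearity_fit()] (the `lm` object is dropped).
#' @param accuracy output of [accuracy_vs_reference()].
#' @return An object of class `sqtlc_validation`.
#' @export
validation_report <- function(specificity = NULL, precision = NULL,
                              linearity = NULL, accuracy = NULL) {
  if (!is.null(linearity)) linearity$fit <- NULL
  if (!is.null(precision)) {
    precision$per_system <- as.list(precision$per_system)
    precision$n <- as.list(precision$n)
  }
  structure(list(specificity = specificity, precision = precision,
                 linearity = linearity, accuracy = accuracy),
            class = "sqtlc_validation")
}

#' @export
print.sqtlc_validation <- function(x, ...) {
  cat("SQ-TLC method validation summary\n")
  if (!is.null(x$specificity))
    cat(sprintf("  specificity: %d/%d Rf pairs within tolerance\n",
                sum(x$specificity$pass), nrow(x$specificity)))
  if (!is.null(x$precision))
    cat(sprintf("  precision:   mean RSD %.2f%% across %d solvent system(s)\n",
                x$precision$mean_rsd, length(x$precision$per_system)))
  if (!is.null(x$linearity))
    cat(sprintf("  linearity:   r = %.4f (slope %.4f, n = %d in range)\n",
                x$linearity$r, x$linearity$slope, x$linearity$n_used))
  if (!is.null(x$accuracy))
    cat(sprintf("  accuracy:    %.1f ± %.1f %% vs reference (r = %.4f, mean deviation %.2f)\n",
                x$accuracy$mean_tlc, x$accuracy$sd_tlc, x$accuracy$r,
                x$accuracy$mean_deviation))
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report an `sqtlc_validation` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
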