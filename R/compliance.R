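#' Classify an API content estimate against pharmacopoeial limits
#'
#' The International Pharmacopoeia assay limit is 90--110 % of label claim
#' (both ends inclusive): that is class `C` (compliant).  Each method carries
#' a borderline margin outside the limits within which an estimate is `BLC`
#' (borderline compliant): 5 percentage points for SQ-TLC (85 <= pct < 90 or
#' 110 < pct <= 115) and 2 for HPLC (88 <= pct < 90 or 110 < pct <= 112).
#' Anything further out is `NC` (noncompliant), with direction `under` or
#' `over`.  A censored estimate ("<50 %", ">120 %") lies beyond both margins
#' and classifies `NC` by its closed endpoint's side, flagged censored.
#'
#' @param pct percent of label claim (vectorised).
#' @param method `"SQTLC"` or `"HPLC"` (sets the borderline margin).
#' @param censored `"none"`, `"low"` or `"high"` (recycled).
#' @param limits compliance window, default `c(90, 110)`.
#' @param margin borderline margin in percentage points; default 5 for
#'   SQ-TLC, 2 for HPLC.
#' @return A data frame with columns `pct`, `method`, `cls` (`"C"`, `"BLC"`,
#'   `"NC"`), `direction` (`"none"`, `"under"`, `"over"`), `censored`.
#' @export
classify_api <- function(pct, method = c("SQTLC", "HPLC"), censored = "none",
                         limits = c(90, 110), margin = NULL) {
  method <- match.arg(method)
  if (is.null(margin)) margin <- if (method == "SQTLC") 5 else 2
  censored <- rep_len(censored, length(pct))
  if (any(!is.na(pct) & pct < 0)) stop("pct must be >= 0", call. = FALSE)
  cls <- character(length(pct)); dir <- character(length(pct))
  for (i in seq_along(pct)) {
    if (censored[i] != "none") {
      cls[i] <- "NC"
      dir[i] <- if (censored[i] == "low") "under" else "over"
      next
    }
    p <- pct[i]
    if (p >= limits[1] && p <= limits[2]) {
      cls[i] <- "C"; dir[i] <- "none"
    } else if (p >= limits[1] - margin && p < limits[1]) {
      cls[i] <- "BLC"; dir[i] <- "under"
    } else if (p > limits[2] && p <= limits[2] + margin) {
      cls[i] <- "BLC"; dir[i] <- "over"
    } else {
      cls[i] <- "NC"; dir[i] <- if (p < limits[1]) "under" else "over"
    }
  }
  data.frame(pct = pct, method = method, cls = cls, direction = dir,
             censored = censored != "none", stringsAsFactors = FALSE)
}

#' Whole-sample verdict of a combination therapy
#'
#' Severity-monotone aggregation of per-component verdicts: a sample is `NC`
#' if at least one component is `NC`; otherwise `BLC` if at least one
#' component is `BLC`; otherwise `C`.  Components without an available
#' reference standard (recorded `NA` or `"—"`) are excluded rather than
#' penalised.  Permutation-invariant.
#'
#' @param classes character vector of component classes (`"C"`, `"BLC"`,
#'   `"NC"`, or `NA`/`"—"` for unassayable components).
#' @return A single class string.
#' @export
aggregate_sample <- function(classes) {
  classes <- classes[!is.na(classes) & !(classes %in% c("—", "-", ""))]
  if (!length(classes)) stop("no assayable component verdicts", call. = FALSE)
  if (!all(classes %in% c("C", "BLC", "NC")))
    stop("component classes must be C, BLC or NC", call. = FALSE)
  if (any(classes == "NC")) "NC"
  else if (any(classes == "BLC")) "BLC"
  else "C"
}

#' Field-versus-reference method concordance
#'
#' Compares paired SQ-TLC and HPLC percent-of-claim values: Pearson
#' correlation of the paired percents, a cross-tabulation of per-API verdict
#' pairs, the per-sample whole-sample verdicts of both methods, and the
#' fraction of samples per group on which the two methods agree.
#'
#' @param records data frame with columns `sample_code`, `api`, `tlc_pct`,
#'   `hplc_pct`, and optionally `group` (product type) for the per-group
#'   agreement breakdown.
#' @param limits,sqtlc_margin,hplc_margin classification parameters, see
#'   [classify_api()].
#' @return An object of class `sqtlc_concordance`: `pearson_r` (`NA` with
#'   `r_defined = FALSE` on zero-variance input), `n_pairs`, `verdict_table`
#'   (cross-tab), `records` (with per-API verdicts), `samples` (per-sample
#'   verdicts and agreement), `group_agreement` (per-group percent of samples
#'   with the same whole-sample verdict).
#' @export
compare_methods <- function(records, limits = c(90, 110),
                            sqtlc_margin = 5, hplc_margin = 2) {
  stopifnot(is.data.frame(records),
            all(c("sample_code", "api", "tlc_pct", "hplc_pct") %in%
                  names(records)))
  if (nrow(records) < 2)
    stop("need >= 2 paired records for a concordance analysis",
         call. = FALSE)
  rec <- records
  rec$tlc_cls <- classify_api(rec$tlc_pct, "SQTLC", limits = limits,
                              margin = sqtlc_margin)$cls
  rec$hplc_cls <- classify_api(rec$hplc_pct, "HPLC", limits = limits,
                               margin = hplc_margin)$cls
  rec$agree <- rec$tlc_cls == rec$hplc_cls
  v_t <- stats::var(rec$tlc_pct); v_h <- stats::var(rec$hplc_pct)
  r_defined <- v_t > 0 && v_h > 0
  r <- if (r_defined) stats::cor(rec$tlc_pct, rec$hplc_pct) else NA_real_
  lv <- c("C", "BLC", "NC")
  tab <- table(factor(rec$tlc_cls, lv), factor(rec$hplc_cls, lv),
               dnn = c("SQTLC", "HPLC"))
  codes <- unique(rec$sample_code)
  samples <- data.frame(
    sample_code = codes,
    group = if ("group" %in% names(rec))
      vapply(codes, function(s) rec$group[rec$sample_code == s][1],
             character(1)) else NA_character_,
    tlc_verdict = vapply(codes, function(s)
      aggregate_sample(rec$tlc_cls[rec$sample_code == s]), character(1)),
    hplc_verdict = vapply(codes, function(s)
      aggregate_sample(rec$hplc_cls[rec$sample_code == s]), character(1)),
    stringsAsFactors = FALSE)
  samples$agree <- samples$tlc_verdict == samples$hplc_verdict
  group_agreement <- if ("group" %in% names(rec)) {
    ag <- tapply(samples$agree, samples$group, mean) * 100
    data.frame(group = names(ag), agreement_pct = as.numeric(ag),
               n = as.integer(table(samples$group)[names(ag)]),
               stringsAsFactors = FALSE)
  } else NULL
  structure(list(pearson_r = r, r_defined = r_defined, n_pairs = nrow(rec),
                 verdict_table = tab, records = rec, samples = samples,
                 group_agreement = group_agreement),
            class = "sqtlc_concordance")
}

#' @export
print.sqtlc_concordance <- function(x, ...) {
  cat(sprintf("Method concordance over %d paired API determinations\n",
              x$n_pairs))
  if (x$r_defined)
    cat(sprintf("  Pearson r (SQ-TLC vs HPLC percent): %.4f\n", x$pearson_r))
  else
    cat("  Pearson r: undefined (zero variance in one method)\n")
  cat(sprintf("  per-API verdict agreement: %d/%d\n",
              sum(x$records$agree), nrow(x$records)))
  cat(sprintf("  whole-sample verdict agreement: %d/%d samples\n",
              sum(x$samples$agree), nrow(x$samples)))
  if (!is.null(x$group_agreement)) {
    cat("  per-group agreement (%):\n")
    for (i in seq_len(nrow(x$group_agreement)))
      cat(sprintf("    %-28s %5.1f (n = %d)\n",
                  x$group_agreement$group[i],
                  x$group_agreement$agreement_pct[i],
                  x$group_agreement$n[i]))
  }
  invisible(x)
}
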