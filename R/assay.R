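#' Run a full semiquantitative TLC assay
#'
#' The package's central estimator.  For every assayable sample-API pair in
#' the manifest it generates (or accepts) 12 replicate plates — 6 per solvent
#' system — quantifies each by the fading-bracket method, aggregates the
#' replicates, and classifies the result against the pharmacopoeial limits.
#'
#' @param manifest data frame of sample-API pairs (see [load_manifest()]),
#'   or an existing `sqtlc_campaign` whose plates should be quantified.
#' @param true_pct true content as percent of claim: single number or named
#'   vector keyed `"<sample_code>:<api>"` (generator ground truth; ignored
#'   when `manifest` is already a campaign).
#' @param template [plate_spec()] template for the generator.
#' @param params [fading_params()].
#' @param seed master seed.
#' @param ... passed to [quantify_plate()] (`min_area`, `contrast_floor`).
#' @return An object of class `sqtlc_assay`: `results` (one row per
#'   sample-API: `sample_code`, `api`, `claim_mg`, `n`, `mean_pct`, `sd_pct`,
#'   per-system means, `censored_n`, `cls`, `direction`, plus `true_pct`
#'   when known), `estimates` (per-replicate list), `n_unusable`, `seed`,
#'   `call`.
#' @examples
#' \donttest{
#' m <- data.frame(sample_code = "DEMO", api = "ATM", claim_mg = 20)
#' fit <- sqtlc_assay(m, true_pct = 75, seed = 42)
#' print(fit)
#' coef(fit)
#' }
#' @export
sqtlc_assay <- function(manifest, true_pct = 100, template = plate_spec(),
                        params = fading_params(), seed = 1L, ...) {
  cl <- match.call()
  campaign <- if (inherits(manifest, "sqtlc_campaign")) manifest
  else generate_campaign(manifest, template = template, seed = seed,
                         true_pct = true_pct)
  keys <- vapply(campaign$plates, function(p)
    paste0(p$meta$sample_code, ":", p$meta$api), character(1))
  estimates <- vector("list", length(campaign$plates))
  usable <- rep(TRUE, length(campaign$plates))
  for (i in seq_along(campaign$plates)) {
    p <- campaign$plates[[i]]
    est <- tryCatch(quantify_plate(p, p$meta$claim_mg, params = params, ...),
                    error = function(e) e)
    if (inherits(est, "error")) {
      usable[i] <- FALSE
    } else {
      est$meta <- p$meta
      estimates[[i]] <- est
    }
  }
  rows <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key & usable)
    if (!length(idx)) next
    meta <- campaign$plates[[idx[1]]]$meta
    summ <- aggregate_replicates(estimates[idx])
    if (summ$censored == "none") {
      cls <- classify_api(summ$mean_pct, "SQTLC")
    } else {
      cls <- classify_api(NA_real_, "SQTLC", censored = summ$censored)
    }
    sm <- summ$system_means
    rows[[length(rows) + 1L]] <- data.frame(
      sample_code = meta$sample_code, api = meta$api,
      claim_mg = meta$claim_mg,
      true_pct = if (!is.null(meta$true_pct)) meta$true_pct else NA_real_,
      n = summ$n, mean_pct = summ$mean_pct, sd_pct = summ$sd_pct,
      mean_pct_s1 = if (!is.null(sm) && "1" %in% names(sm)) sm[["1"]]
        else NA_real_,
      mean_pct_s2 = if (!is.null(sm) && "2" %in% names(sm)) sm[["2"]]
        else NA_real_,
      censored_n = summ$censored_n, censored = summ$censored,
      cls = cls$cls, direction = cls$direction,
      stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(results = results, estimates = estimates,
                 n_unusable = sum(!usable), seed = campaign$seed, call = cl,
                 params = params),
            class = "sqtlc_assay")
}

#' @export
print.sqtlc_assay <- function(x, ...) {
  cat("Semiquantitative TLC fading assay\n")
  cat("Call: "); print(x$call)
  if (is.null(x$results)) { cat("  (no usable results)\n"); return(invisible(x)) }
  for (i in seq_len(nrow(x$results))) {
    r <- x$results[i, ]
    if (r$censored == "none")
      cat(sprintf("  %s %s (%g mg): %.1f ± %.1f %% of claim [%s], n = %d\n",
                  r$sample_code, r$api, r$claim_mg, r$mean_pct, r$sd_pct,
                  r$cls, r$n))
    else
      cat(sprintf("  %s %s (%g mg): censored (%s), n = %d [%s]\n",
                  r$sample_code, r$api, r$claim_mg, r$censored, r$n, r$cls))
  }
  if (x$n_unusable > 0)
    cat(sprintf("  %d unusable replicate plate(s) rejected\n", x$n_unusable))
  invisible(x)
}

#' @export
summary.sqtlc_assay <- function(object, ...) {
  res <- object$results
  structure(list(results = res,
                 n_pairs = if (is.null(res)) 0L else nrow(res),
                 n_replicates = sum(res$n),
                 n_censored = sum(res$censored_n),
                 n_unusable = object$n_unusable,
                 verdicts = if (!is.null(res)) table(res$cls) else NULL,
                 seed = object$seed),
            class = "summary.sqtlc_assay")
}

#' @export
print.summary.sqtlc_assay <- function(x, ...) {
  cat(sprintf(paste0("SQ-TLC assay summary: %d sample-API pair(s), ",
                     "%d replicates (%d censored, %d unusable), seed %d\n"),
              x$n_pairs, x$n_replicates, x$n_censored, x$n_unusable, x$seed))
  if (!is.null(x$verdicts)) {
    cat("  verdicts: ")
    cat(paste(sprintf("%s = %d", names(x$verdicts), x$verdicts),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.sqtlc_assay <- function(object, ...) {
  res <- object$results
  if (is.null(res)) return(numeric(0))
  stats::setNames(res$mean_pct, paste0(res$sample_code, ":", res$api))
}

#' Plot an assay result
#'
#' Draws the estimated percent-of-claim interval (mean ± sd across
#' replicates) per sample-API against the compliance window, with the true
#' content overplotted when known (synthetic campaigns).
#'
#' @param x an `sqtlc_assay`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.sqtlc_assay <- function(x, ...) {
  res <- x$results[x$results$censored == "none", , drop = FALSE]
  if (is.null(res) || nrow(res) == 0) {
    warning("nothing to plot (all results censored)")
    return(invisible(x))
  }
  n <- nrow(res)
  ylim <- range(c(res$mean_pct - res$sd_pct, res$mean_pct + res$sd_pct,
                  85, 115, res$true_pct), na.rm = TRUE)
  graphics::plot(seq_len(n), res$mean_pct, ylim = ylim, pch = 19,
                 xaxt = "n", xlab = "", ylab = "% of label claim",
                 main = "SQ-TLC fading assay", ...)
  graphics::axis(1, at = seq_len(n),
                 labels = paste(res$sample_code, res$api), las = 2,
                 cex.axis = 0.7)
  has_spread <- res$sd_pct > 0
  if (any(has_spread))
    graphics::arrows(seq_len(n)[has_spread],
                     (res$mean_pct - res$sd_pct)[has_spread],
                     seq_len(n)[has_spread],
                     (res$mean_pct + res$sd_pct)[has_spread],
                     angle = 90, code = 3, length = 0.03)
  graphics::abline(h = c(90, 110), lty = 2)
  graphics::abline(h = c(85, 115), lty = 3, col = "grey50")
  if (any(!is.na(res$true_pct)))
    graphics::points(seq_len(n), res$true_pct, pch = 4, col = 2)
  invisible(x)
}
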