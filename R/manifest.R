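#' Load a product-composition manifest
#'
#' Expands a composition table (one row per product category: API codes,
#' label claims, product counts) into a per-sample-per-API manifest with
#' synthetic sample codes.  The bundled fixture
#' `system.file("extdata", "table1_composition.csv", package = "sqtlc")`
#' describes a surveyed market basket of 112 antimalarial products: 36
#' non-artemisinin products, 4 copacked artesunate + sulphadoxine-
#' pyrimethamine blisters and 72 fixed-dose artemisinin combinations.
#'
#' Column `assayable` marks sample-API pairs the field assay can actually
#' measure: it is `FALSE` for APIs without an available reference standard
#' (piperaquine, sulphamethoxypyridazine) and for every API of a sample
#' category flagged infeasible on TLC (quinine sulphate).
#'
#' @param path composition CSV with columns `category`, `therapy_type`,
#'   `dosage_form`, `n_products`, `apis` (semicolon-separated codes),
#'   `claims_mg` (semicolon-separated), `has_reference`
#'   (semicolon-separated TRUE/FALSE), `sqtlc_feasible` (per category).
#'   Defaults to the bundled fixture.
#' @return A data frame of class `sqtlc_manifest`, one row per sample-API:
#'   `sample_code`, `category`, `therapy_type`, `dosage_form`, `api`,
#'   `claim_mg`, `has_reference`, `sqtlc_feasible`, `assayable`.  Attribute
#'   `counts` holds the headline tallies (see [manifest_counts()]).
#' @export
load_manifest <- function(path = system.file("extdata",
                                             "table1_composition.csv",
                                             package = "sqtlc")) {
  comp <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "therapy_type", "dosage_form", "n_products",
            "apis", "claims_mg", "has_reference", "sqtlc_feasible")
  if (!all(need %in% names(comp)))
    stop("composition table lacks columns: ",
         paste(setdiff(need, names(comp)), collapse = ", "), call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(comp))) {
    apis <- strsplit(comp$apis[i], ";")[[1]]
    claims <- as.numeric(strsplit(comp$claims_mg[i], ";")[[1]])
    hasref <- as.logical(strsplit(comp$has_reference[i], ";")[[1]])
    stopifnot(length(apis) == length(claims),
              length(apis) == length(hasref))
    for (s in seq_len(comp$n_products[i])) {
      code <- sprintf("P%02d_%03d", i, s)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_code = code, category = comp$category[i],
        therapy_type = comp$therapy_type[i],
        dosage_form = comp$dosage_form[i],
        api = apis, claim_mg = claims, has_reference = hasref,
        sqtlc_feasible = comp$sqtlc_feasible[i],
        stringsAsFactors = FALSE)
    }
  }
  m <- do.call(rbind, rows)
  m$assayable <- m$has_reference & m$sqtlc_feasible
  class(m) <- c("sqtlc_manifest", "data.frame")
  attr(m, "counts") <- manifest_counts(m)
  m
}

#' Headline counts of a manifest
#'
#' Reports the tallies under the conventions the survey used:
#' \describe{
#'   \item{n_products}{distinct products in the basket.}
#'   \item{n_products_excluded}{products dropped entirely from the paired
#'     SQ-TLC/HPLC analysis: TLC-infeasible categories (quinine sulphate)
#'     plus products containing a non-stainable API
#'     (sulphamethoxypyridazine).}
#'   \item{n_products_both_methods}{products analysed by both methods.}
#'   \item{n_assayable_apis}{sample-API pairs with an available reference
#'     standard, over all TLC-feasible product categories (components of a
#'     multi-API product remain countable even when a sibling component is
#'     not).}
#' }
#' The two exclusion conventions differ deliberately: a product containing a
#' non-stainable API cannot receive a whole-sample verdict from both methods,
#' but its other components are still individually assayable.
#'
#' @param manifest a manifest from [load_manifest()].
#' @return A named list of counts.
#' @export
manifest_counts <- function(manifest) {
  per_sample <- unique(manifest[, c("sample_code", "category",
                                    "sqtlc_feasible")])
  n_products <- nrow(per_sample)
  has_unassayable_api <- tapply(
    !manifest$has_reference &
      manifest$api %in% c("SM"),   # non-stainable component
    manifest$sample_code, any)
  excluded <- !per_sample$sqtlc_feasible |
    has_unassayable_api[per_sample$sample_code]
  n_excluded <- sum(excluded)
  feasible <- manifest$sqtlc_feasible & manifest$has_reference
  list(n_products = n_products,
       n_products_excluded = as.integer(n_excluded),
       n_products_both_methods = as.integer(n_products - n_excluded),
       n_assayable_apis = as.integer(sum(feasible)))
}

#' Restrict a manifest to products analysed by both methods
#'
#' Drops TLC-infeasible categories and products containing a non-stainable
#' API, then keeps only assayable sample-API rows.
#'
#' @param manifest a manifest from [load_manifest()].
#' @return The filtered manifest (same class).
#' @export
apply_exclusions <- function(manifest) {
  bad_sample <- tapply(!manifest$sqtlc_feasible |
                         (!manifest$has_reference & manifest$api == "SM"),
                       manifest$sample_code, any)
  keep <- !bad_sample[manifest$sample_code] & manifest$assayable
  out <- manifest[keep, , drop = FALSE]
  attr(out, "counts") <- manifest_counts(manifest)
  out
}

#' @export
print.sqtlc_manifest <- function(x, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("Sample manifest: %d rows (sample-API pairs)\n", nrow(x)))
  if (!is.null(cts))
    cat(sprintf(paste0("  %d products; %d excluded from paired analysis; ",
                       "%d analysed by both methods; %d assayable APIs\n"),
                cts$n_products, cts$n_products_excluded,
                cts$n_products_both_methods, cts$n_assayable_apis))
  invisible(x)
}

#' Bundled method-comparison table
#'
#' Loads the transcribed paired SQ-TLC/HPLC determinations (39 sample-API
#' rows: percent of claim, reported spread and the printed compliance remark
#' for both methods).
#'
#' @return A data frame with columns `sample_code`, `api`, `group`,
#'   `claim_mg`, `tlc_pct`, `tlc_sd`, `tlc_remark`, `hplc_pct`, `hplc_sd`,
#'   `hplc_remark`.
#' @export
read_method_comparison <- function() {
  utils::read.csv(system.file("extdata", "table3_method_comparison.csv",
                              package = "sqtlc"), stringsAsFactors = FALSE)
}

#' Bundled per-sample verdict table
#'
#' Loads the transcribed combination-therapy verdict table: per-component
#' classes (in label-claim order, `—` marking components without a reference
#' standard) and the printed whole-sample verdict, for both methods.
#' A literal duplicate row in the source is removed with a warning.
#'
#' @return A data frame with columns `sample_code`, `label_claim`,
#'   `tlc_components`, `tlc_overall`, `hplc_components`, `hplc_overall`
#'   (component lists are `|`-separated).
#' @export
read_sample_verdicts <- function() {
  t4 <- utils::read.csv(system.file("extdata", "table4_sample_verdicts.csv",
                                    package = "sqtlc"),
                        stringsAsFactors = FALSE)
  dup <- duplicated(t4)
  if (any(dup)) {
    warning("removing ", sum(dup), " duplicated verdict row(s): ",
            paste(unique(t4$sample_code[dup]), collapse = ", "),
            call. = FALSE)
    t4 <- t4[!dup, , drop = FALSE]
  }
  t4
}
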