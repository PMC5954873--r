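# shared fixture builders; everything generated in code at test time

quiet_spec <- function(...) plate_spec(noise_sd = 0, background_tilt = 0, ...)

# plate with a known true content (% of claim) in the test lane
content_spec <- function(true_pct, ...) {
  spec <- plate_spec(...)
  spec$amounts_ug[length(spec$amounts_ug)] <- true_pct / 100 * 2
  spec
}

# hand-built plate object around a raw pixel matrix (for degenerate inputs)
raw_plate <- function(pixels, layout) {
  structure(list(pixels = pixels, layout = layout, truth = NULL, spec = NULL,
                 provenance = list(source = "test"), solvent_system_id = NA),
            class = "sqtlc_plate")
}

demo_manifest <- function(n_samples = 1, apis = "ATM", claim = 20) {
  base <- data.frame(sample_code = character(), api = character(),
                     claim_mg = numeric(), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(n_samples), function(s)
    data.frame(sample_code = sprintf("T%02d", s), api = apis,
               claim_mg = claim, stringsAsFactors = FALSE))
  do.call(rbind, c(list(base), rows))
}

# independent two-pass Pearson correlation (textbook formula)
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
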