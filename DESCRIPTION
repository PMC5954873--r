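Package: sqtlc
Title: Semiquantitative Thin-Layer Chromatography by Spot Fading
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the active pharmaceutical ingredient (API) content of
    a test spot on a scanned thin-layer chromatography (TLC) plate by
    bracketing it within a graded reference-standard dilution series under a
    brightness-sweep fading operator.  Includes a seeded synthetic plate
    generator with exact ground truth, spot detection and retention-factor
    computation, pharmacopoeial compliance classification (90-110 percent of
    label claim with method-specific borderline margins), field-versus-reference
    method concordance analysis, and ICH-style validation statistics
    (specificity, precision, linearity, accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
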