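---
title: "Semiquantitative TLC by spot fading: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiquantitative TLC by spot fading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqtlc)
```

## The assay

Semiquantitative thin-layer chromatography (SQ-TLC) estimates how much
active pharmaceutical ingredient (API) a medicine really contains, using
nothing more than a TLC plate, a reference standard (RS) and a scanner.  A
fixed 2 µL spot of a 1 mg/mL extract of the dosage form is developed
alongside a graded RS series — 1.0, 1.2, …, 2.4 µL of a 1 mg/mL standard
solution, so that volume in µL equals mass in µg.  After visualisation, the
brightness of the scanned chromatogram is raised step by step.  Spots fade
in order of how much substance they carry: the lighter a spot, the earlier
it disappears.  The test spot's API amount is bracketed by the largest RS
amount that disappears *with or before* it (the lower limit) and the next
RS amount up, which outlasts it (the upper limit).

Because the test spot is 2.0 µL of a nominally 1 mg/mL solution, an RS
amount of $a$ µg converts to percent of label claim as
$\mathrm{pct} = a / 2.0 \times 100$, and to mass as
$\mathrm{mg} = \mathrm{pct} / 100 \times \mathrm{claim}$.  A bracket of
[1.4, 1.6] µg on a 200 mg claim is therefore 70–80 % of claim, i.e.
140–160 mg.  Each determination is replicated 12 times, 6 in each of two
solvent systems, and the replicate midpoints are averaged.

The series only supports claims between 50 % (1.0 µg) and 120 % (2.4 µg):
a test spot fading before the smallest RS spot is reported "<50 %", one
outlasting the largest is ">120 %".  Both are censored, one-sided results.

## The fading operator

"Raising the brightness" is mechanised as the clipped additive map
$p \mapsto \min(p + b, 1)$ applied to every pixel (grayscale, 0 = black,
1 = white), the effect of an office image tool's brightness slider.  A spot
region is *visible* at offset $b$ while its contrast — background minus
pixel, both brightened — still reaches the visibility threshold
$\varepsilon$ (default 0.02).  Sweeping $b$ from 0 in steps of 1/255 (one
8-bit level) up to 1 yields, per spot, a nonincreasing contrast curve and
the disappearance threshold $b^\*$: the first sweep offset at which the
contrast drops below $\varepsilon$.  Visibility is judged on the *peak*
contrast of the region by default (a spot is visible as long as any part of
it is); an integrated (mean-contrast) mode is available.

Two refinements matter in practice, and both are applied by
`quantify_plate()`:

* **Flat-field correction.**  Under the additive sweep, a spot sitting on a
  brighter part of the plate clips to white earlier than an equally dark
  spot elsewhere, so a background gradient would bend the ruler.  The
  estimated background is therefore divided out additively before the
  sweep, leaving every deficit on a uniform white field, and the flattened
  image is lightly Gaussian-smoothed (σ = 2.5 px), emulating the spatial
  averaging of visual inspection.  Both operations rescale all lanes
  equally, so the ordinal comparison between lanes is untouched.

* **Sub-step crossing refinement.**  The sweep grid quantises $b^\*$ up to
  a full 1/255 step.  Two spots whose true crossings differ by less than a
  step then collide onto the same grid value and would be declared to "fade
  at the same time" even though one is measurably lighter — an artifact of
  the mechanisation, absent from the continuous visual comparison the assay
  imitates.  `fading_threshold()` therefore also returns the linearly
  interpolated visibility crossing (`b_star_refined`), and lanes are
  compared on these refined values, where simultaneity reduces to numerical
  equality.  The grid-valued `b_star` (with its one-step tie tolerance)
  remains the reported threshold and governs direct uses of
  `bracket_estimate()` on grid values.

## Bracketing rules

`bracket_estimate()` supports two readings of a simultaneous fade.  The
default (`tie_rule = "lower"`) follows the assay's reading procedure: the RS
spot fading simultaneously with the test marks the *lower* limit, and the
next RS up — which fades after the test — the upper limit, so the output is
always a genuine interval.  The alternative (`tie_rule = "point"`) collapses
a simultaneous fade to the degenerate bracket $[a_i, a_i]$, a point estimate
at the matching RS amount.  The interval reading is the default because it
is what produces the worked-scheme outputs ("between 1.4 and 1.6 µL") and
because a zero-width bracket can never contain a continuously distributed
true content, which would misstate the method's coverage.

A reference series whose thresholds are not nondecreasing in amount (after
allowing one sweep step of discretisation slack) indicates a failed plate;
the replicate is rejected as unusable rather than bracketed.

## The synthetic plate generator

`generate_plate()` renders the study conditions so every stage is testable
without laboratory data.  A plate is a light background (default gray 0.9,
with a mild horizontal gradient of amplitude 0.05) minus one Gaussian
darkness deficit per spotted lane (σ = 6 px), plus additive Gaussian pixel
noise (sd 0.01), clamped to [0, 1].  Nine lanes 40 px apart hold the eight
RS amounts 1.0–2.4 µg and, last, the test spot, whose amount encodes the
true content: $\mathrm{true\ pct} / 100 \times 2.0$ µg.  Spot centres sit at
the row implied by each lane's retention factor; the two solvent systems of
a campaign use different retention factors (0.45 and 0.60) to emulate
per-system migration.

Peak darkness follows a saturating-linear response in the spotted amount
$a$: $d_0 + k\,\min(a, a_{\mathrm{knee}})$ with a compressed tail of slope
$k/8$ beyond the knee (defaults $d_0 = 0.10$, $k = 0.25$ per µg).  The
response is linear across the assay's declared 1.0–2.0 µg working range.
The knee defaults to 2.4 µg, the top of the RS series: placing it inside
the series would make the top RS interval degenerate (two RS spots one
brightness step apart), destroying the 110–120 % resolution the censoring
rule relies on, while the shallow tail beyond 2.4 µg still separates a
grossly overdosed test spot (>120 %) from the largest RS spot.  The
increment of the RS series is 0.2 µg, consistent with the reported bracket
limits (1.4, 1.6, 2.0, 2.4); it is configurable.

What the generator deliberately does *not* model: solvent-migration
physics, spray-reagent colour (staining colour is metadata only), plate
batch effects, scanner vignetting beyond the planar gradient, or spatially
correlated noise.  Passing tests on synthetic plates therefore demonstrate
the correctness of the measurement chain under the stated image model, not
robustness to every artefact a real scan can carry.

## Plate reading

The background is estimated from the 90th-percentile profile of each column
and each row, smoothed and combined additively — robust so long as spots
occupy a minority of every row and column, which any sane layout satisfies.
A scan in which most pixels sit far below the estimated background (one
large dark blob) is flagged low-confidence.  Spots are the connected
components of pixels at least `contrast_floor` (0.05) below the background
with at least `min_area` (20) pixels; centroids are contrast-weighted.  The
origin and solvent front come from the layout sidecar — the analyst marks
them in practice; they are never auto-detected.  Detections are assigned to
the nearest application column within a half lane width, ties breaking
toward the lower lane index (flagged); the strongest detection per lane is
the primary spot, extras are counted as potential degradation products.
A merged region containing two well-separated local contrast maxima is
flagged multi-peak rather than split.

The retention factor of a detection is
$R_f = (y_{\mathrm{origin}} - y_{\mathrm{centroid}}) /
(y_{\mathrm{origin}} - y_{\mathrm{front}})$; values outside [0, 1] are
legal but flagged.  Specificity checks compare test and RS retention
factors with a default tolerance of 0.05 — a conventional figure for
"very similar" migration, since no numeric criterion is standard.

## Compliance classification

The pharmacopoeial assay window is 90–110 % of label claim, both ends
inclusive (class C).  Outside it, each method has a borderline-compliant
margin reflecting its precision: 5 percentage points for SQ-TLC
(85 ≤ pct < 90 or 110 < pct ≤ 115) and 2 for HPLC (88 ≤ pct < 90 or
110 < pct ≤ 112), both outer edges inclusive; beyond that the sample is
noncompliant, with an over/under direction.  Censored estimates ("<50 %",
">120 %") lie beyond both margins and classify NC by the side of their
closed endpoint.  A combination therapy is NC if any component is NC, else
BLC if any component is BLC, else C; components without an available
reference standard (piperaquine, sulphamethoxypyridazine) are excluded from
the aggregation rather than treated as failures.

## Replication and statistics

Replicate midpoints are summarised as mean ± sample standard deviation
(n − 1 denominator; the estimator behind reported "±" values is not
standardised, and sd is the conservative conventional choice), with
per-solvent-system means and a count of censored replicates, which are
excluded from the moments.  Averaging bracket endpoints before or after the
percent conversion commutes, because the conversion is linear.  Precision
is the relative standard deviation per solvent system (n = 6), averaged;
linearity is an ordinary least-squares fit of the fading signal on amount,
restricted to 1.0–2.0 µg; accuracy is the mean signed deviation from a
reference method plus the Pearson correlation.  Concordance between SQ-TLC
and HPLC uses the Pearson correlation of paired percents, a cross-table of
per-API verdict pairs, and the per-group fraction of samples receiving the
same whole-sample verdict.

## Numerical choices and degenerate inputs

* Sweep step 1/255, cap 1.0; the threshold grid is exact multiples of the
  step, so tolerance comparisons shave an ulp-scale margin to stay stable.
* Percent conversion is exact rational arithmetic up to floating
  representation (lower_pct × 2 = lower_ug × 100 to 1e-12).
* Empty spot regions, zero-variance inputs to correlation or OLS, layouts
  with coincident origin and front, nonpositive claims, and empty replicate
  sets all raise informative errors; an all-censored replicate set yields a
  censored summary with a direction rather than a number.
* A blank test lane yields a censored-low estimate flagged
  "no spot detected"; a missing RS lane rejects the whole replicate.

## Problem sizes

The bundled tests and the acceptance script run campaigns of 12 replicate
plates per sample-API pair on 400 × 200 px plates, and the bracket-recovery
experiment uses 200–250 independent seeded plates with true contents drawn
uniformly from 55–115 % of claim.  These sizes exercise every code path
while keeping a full run in the order of a minute on one CPU; all
generator parameters scale up without code changes.

## Known limitations

* The method is ordinal by construction: resolution is one RS increment
  (10 % of claim), and contents outside 50–120 % are only bounded, not
  estimated.  Samples estimated between 80 % and 120 % should be confirmed
  by a quantitative method.
* The laboratory study's headline figures (correlation over all surveyed
  APIs, pooled accuracy/precision, instrument linearity) depend on raw
  laboratory data that are not redistributable; this package demonstrates
  the same computations on the transcribed comparison subset and on
  synthetic campaigns instead.
* Stability testing is a laboratory protocol; only its bookkeeping
  (retest values against limits) is representable here.
* No plate warping, lane auto-calibration or multi-spot purity analysis:
  extra spots per lane are counted, not characterised.
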