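---
title: "Assessing Vulnerable Marine Ecosystems from single seafloor images"
author: "vmeassess authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing Vulnerable Marine Ecosystems from single seafloor images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Regional fisheries management bodies (RFMO/As) must identify Vulnerable
Marine Ecosystems (VMEs) — cold-water coral reefs, octocoral gardens,
sponge grounds, sea-pen fields, xenophyophore aggregations, chemosynthetic
communities — and protect them from significant adverse impacts by bottom
fisheries. The conventional evidence is fisheries bycatch, which is itself
destructive and badly biased toward robust taxa. Annotated seafloor imagery
is the non-destructive alternative, but it needs three ingredients this
package supplies:

1. **A registry of indicator taxa.** Which taxa count as VME indicators
   differs by management body, both in membership and in taxonomic rank.
   `VmeRegistry` encodes the per-body lists, including *qualified* listings
   ("only Cerianthidae", "stalked only", "as Hexactinellida &
   Demospongiae"), and supports consensus operations across bodies.
2. **A transparent decision rule for a single image.** `classifyImages()`
   implements a deterministic, short-circuiting flow chart that maps image
   evidence onto the five FAO VME criteria (uniqueness/rarity, functional
   significance, fragility, slow-recovery life history, structural
   complexity); meeting any one criterion suffices.
3. **Calibrated thresholds.** The flow chart's last three steps compare
   richness and densities against thresholds. `runCalibrationReport()`
   derives candidate thresholds from images that experts have labelled
   Yes/Maybe/No ("is this a VME?") and quantifies how well the labels
   separate statistically.

## Data model

A `VmeImageSet` extends `SummarizedExperiment`: one column per image, one
row per annotated taxon, a single integer `counts` assay, and per-image
metadata in `colData` — laboratory, site, optional region, depth (m),
imaged area `A` (m²), percent hard substrate, camera, the optional expert
label, and five boolean evidence flags (reef present, chemosynthetic taxa
present, large/old individual present, visible functional role, threatened
taxon present). The flags are annotator judgements: whether a colony is
likely over a century old, or whether egg cases are attached, are expert
visual calls that cannot be recomputed from a count table, so the engine
never infers them.

`computeDensities()` turns counts into a `VmeDensitySet`: per-taxon density
`d_t = n_t / A` (individuals/m²), overall indicator density `D = Σ_t d_t`,
richness `S` (number of indicator taxa present) and richness density `S/A`
(taxa/m²). Only taxa that resolve to registry indicators under the chosen
body/consensus and policy contribute; annotation columns that resolve to
the same canonical taxon (e.g. `Gorgonacea` and `Alcyonacea`) are pooled
first.

## The decision flow chart

Step 0 is element detection: an image with no indicator counts and no
flags yields `NO_EVIDENCE_EVALUATE_MORE` — detecting nothing in one frame
says little about the site. With evidence present, the steps run in fixed
order and the first "Yes" ends evaluation:

| step | trigger | FAO criteria attached |
|---|---|---|
| 1 | reef present (live or dead, coral or sponge) | all five |
| 2 | chemosynthetic ecosystem taxa | uniqueness/rarity, functional significance, fragility, life history |
| 3 | large/old individual | uniqueness/rarity, functional significance, fragility |
| 4 | visible functional role (nursery, spawning, egg attachment) | functional significance |
| 5 | threatened taxon | uniqueness/rarity, functional significance |
| 6 | `S ≥ tau_S` | structural complexity |
| 7 | `d_t ≥ tau_d[t]` for any configured taxon | structural complexity |
| 8 | `D ≥ tau_D` | structural complexity |

If nothing fires the verdict is `NOT_VME_THIS_IMAGE`, again with the
guidance that more images should be evaluated before concluding absence.
Two deliberately open points are configurable rather than hard-coded: the
step order follows the prose description of the chart (flag steps before
density steps), and the richness step uses the raw count `S` by default
with `richness_metric = "per_area"` available, because survey practice is
split on whether "number of indicators" should be area-standardised.

Monotonicity holds by construction: raising any count or setting any flag
can only move a verdict toward VME, never away from it. The property tests
verify totality, short-circuiting and monotonicity on tens of thousands of
randomized annotations.

## Thresholds

`ThresholdConfig` carries `tau_S` (taxa), per-taxon `tau_d` and combined
`tau_D` (individuals/m²). The packaged defaults are midpoints of the
calibration Yes/No group means — Alcyonacea 0.88, Scleractinia 2.035,
Porifera 0.935, combined 4.16 individuals/m², `tau_S` = 3 taxa — and are
explicitly placeholders: density that constitutes a "significant
concentration" is taxon- and region-dependent, so the intended workflow is
to re-derive thresholds from regional labelled data and override the YAML
config. Three estimators are provided:

* `midpoint_means`: `(mean(Yes) + mean(No)) / 2` — symmetric, sensitive to
  skew.
* `no_quantile`: the q-th quantile of the No group (default 0.95), a
  "beyond what experts dismiss" rule; lower-interpolation (`type = 1`) so
  the estimate is always an observed value.
* `min_misclassification`: the cut minimising false-VME plus missed-VME
  calls over observed values, calling VME when the value exceeds the cut;
  ties break toward the lower cut, so perfectly separated groups return
  `max(No)`, the infimum of the zero-error gap.

Maybe-labelled images are excluded from threshold derivation (a threshold
contrasts a clear Yes with a clear No) but included in summaries, ANOVA
and Tukey contrasts, which test all three labels.

## Calibration statistics

The calibration run applies, in order: the area filter; density
computation; ordinary least-squares regressions of overall density on
depth and on percent *soft* substrate (computed as 100 − percent hard,
since hard cover is what annotators record); then per-label summaries
(sample SD, n−1 denominator), one-way ANOVA and Tukey HSD for richness
per m², each indicator taxon present, and overall density. ANOVA and Tukey
are delegated to `stats::aov()`/`stats::TukeyHSD()` (Tukey–Kramer for
unequal group sizes); the test suite checks them against independent
direct-summation and pooled-*t* oracles rather than trusting either route
alone. No multiple-testing correction is applied across metrics — the
report states the number of tests run so users can adjust, matching the
per-metric reporting convention of calibration exercises in this field.

Numerical choices: the identity `D = Σ_t d_t` is asserted to 1e−9
absolute (pure arithmetic, tight bound); an all-constant response is
reported as `F = 0, p = 1` and a constant regression response as
`slope = 0, p = 1` rather than the 0/0 noise the generic fitters produce;
Tukey pairs with zero pooled variance get `p = 1` when the group means
coincide and `p = 0` when they differ. The area filter removes images
strictly below 1 m² — an image of exactly 1 m² is kept; that boundary
convention is asserted in the tests.

The richness/density analysis defaults to the **union** of all bodies'
indicator lists under the `qualified_counts` policy (a qualified listing
names taxa with members that are indicators, so it counts). Which list a
given analysis should use is genuinely regional; both the body and the
policy are arguments everywhere.

## The synthetic generator

`generateAnnotations()` emulates the structure of a compiled multi-team
calibration dataset so every pipeline stage is testable without survey
data: 10 laboratories, 27 sites, ~50 images per site (1,273 images in the
`study_like` fixture), areas log-uniform on 0.25–50 m² with a 38/1273
sub-1 m² fraction, depths uniform on 100–4,176 m. Counts for each taxon
group are negative-binomial with mean `density × A` and size 0.2; the NB
family was chosen because reported per-label density SDs exceed their
means several-fold, which Poisson counts cannot produce, and the size
default reproduces SD/mean ratios of roughly 2–3 at typical image areas.
Per-label group means default to the published calibration values where
printed; Maybe means without a printed value are the Yes/No midpoint. The
named group means for Yes sum to slightly more than the printed overall
Yes mean, so the residual "other taxa" group (represented by Pennatulacea)
gets `max(0, overall − sum(named))` per label — the generated overall Yes
density is therefore ~6.35 rather than 6.00 individuals/m², and recovery
tests target the per-group configured means, which are self-consistent.

What the generator does **not** emulate: within-site spatial correlation
(a site-level log-normal density multiplier exists but defaults to off,
since its magnitude is unquantified), label assignment as a *function* of
the image content (labels are drawn first and densities conditioned on
them, the reverse of how experts actually judge), taxon co-occurrence
structure, percent-cover reef annotation, and camera effects. Passing
tests on synthetic data therefore demonstrate that the statistical
machinery is correct under the stated sampling structure — not that real
survey data meet ANOVA assumptions, which heavily skewed zero-inflated
densities generally do not.

Richness is emergent (whichever counts are non-zero), not directly
simulated, so printed richness means are order checks (No < Yes ≤ Maybe),
not exact targets.

## Problem sizes used by the test suite

The shipped tests run the oracle-equivalence properties on 500 random
small instances, type-I calibration on 1,000 regenerations of the
300-image `null_labels` fixture, parameter recovery on a 20,000-image
draw, and the flow-chart properties on 10,000 randomized annotations —
sizes chosen so the whole suite completes in a couple of minutes while
keeping Monte-Carlo standard errors far below the assertion margins.

## Known limitations

* The registry stores ambiguous source wordings (e.g. a family listed "as"
  a *higher* rank) verbatim with a flag instead of interpreting them;
  `resolveTaxon()` only walks named qualifiers and the synonym table, not
  a full taxonomic backbone.
* Single-image verdicts say nothing about areal extent; aggregating
  multiple images into site-level designations, and any confidence index
  over them, is out of scope.
* Percent-cover metrics for reef framework are not supported; counts are
  strictly integers.
* The flow chart treats expert evidence flags as ground truth; it has no
  notion of annotator disagreement.
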