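---
title: "Methods: pattern quantification, grading engines and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern quantification, grading engines and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luadgrade)
```

## The quantification model

A segmentation model assigns every tumor pixel of a whole-slide image one
of six LUAD growth patterns. The package starts downstream of that step,
from integer label masks. Pattern abundance is measured in *corrected
area*: for pattern $p$ with raw pixel count $n_p$ and correction weight
$w_p$,

$$A_p = n_p \, w_p \, \left(\tfrac{\mathrm{mpp}}{1000}\right)^2
\quad\text{(mm}^2\text{, when the pixel scale is known)},
\qquad \mathrm{pct}_p = 100 \, A_p / \textstyle\sum_q A_q .$$

The weights ($w_{lepidic}=1.41$, $w_{acinar}=1.35$, $w_{papillary}=1.06$,
$w_{micropapillary}=1.14$, $w_{solid}=1.0$, $w_{cg}=1.10$) are
dimensionless multipliers that compensate for the lower epithelial
tumor-cell density of low-grade growth: a pixel of lepidic area contains
less tumor than a pixel of solid area, so raw pixel shares understate
low-grade patterns. They are calibration constants, not tuning knobs; the
whole pipeline degenerates to raw pixel percentages under
`unit_weights()`. Weights are applied to *areas before percentages are
formed*, at whatever raster is quantified — per-ROI or per-WSI. The
default workflow applies them per slide (WSI level) and then pools; since
each pixel is weighted once by its own pattern, ROI-level and slide-level
application give identical case totals unless ROIs are re-normalized
in between.

Background pixels are excluded from all totals; an all-background mask
yields an empty composition with a flag rather than an error. Multi-slide
cases sum weighted areas across slides and recompute percentages
(area-weighted pooling), so a large slide dominates a small biopsy
fragment — a deliberate choice consistent with reporting absolute areas;
averaging slide percentages would weight a 2 mm fragment like a full
section.

**Dominant and secondary pattern.** The dominant pattern maximizes the
weighted percentage. Ties are broken toward the more severe pattern under
the fixed total order lepidic < acinar < papillary < complex glandular <
micropapillary < solid — the conservative clinical call, and configurable
through the codebook. The secondary pattern is the runner-up subject to a
floor of 5% abundance (the conventional reporting threshold for a
mentioned pattern; `min_secondary_pct` is exposed). When no other pattern
reaches the floor, the Gleason convention applies: the secondary is set
to the dominant and flagged as a proxy, so a purely-acinar tumor scores
2 + 2, not 2 + missing.

## The grading engines

All six engines are pure functions of the case composition and share one
vectorized rule core, so batch grading of tens of thousands of
compositions is instantaneous and a scalar call is the one-row special
case of the batch path.

* **WHO**: three-tier grade of the dominant pattern.
* **IASLC**: WHO base grade; G1/G2 upgraded to G3 when
  micropapillary + solid + complex glandular exceeds 20% *strictly* — a
  composition at exactly the threshold is not upgraded. The strict
  inequality matches the "more than 20%" phrasing of the rule; boundary
  compositions are rare in practice but common on evaluation grids, so
  the convention matters for reproducibility.
* **Simplified IASLC**: complex glandular leaves the upgrade sum (its
  prognostic profile is closer to the intermediate patterns); dominant
  complex glandular is still G3 via the base grade.
* **Modified IASLC**: threshold 50% — up to half the tumor may be
  high-grade patterns if none of them dominates.
* **Four-tier**: dominant-pattern grading with complex glandular as its
  own G3 between acinar/papillary (G2) and micropapillary/solid (G4).
* **Prognostic score**: sum of the three-tier grades of dominant and
  secondary. Score 3 splits into 3a (1 + 2) and 3b (2 + 1); groups are
  PG1 = 3a, PG2 = 3b, PG3 = 4, PG4 = 5, PG5 = 6. Score 4 pools (2 + 2),
  (1 + 3) and (3 + 1), and score 5 pools (2 + 3) and (3 + 2) — Gleason
  sum semantics: only the score-3 split distinguishes pattern order.
  Purely lepidic tumors (score 2) are emitted as PG0 with a flag rather
  than dropped; they are rarely relevant in routine diagnostics but the
  group is well defined. A four-tier-scored variant (complex glandular as
  its own tier, scores 2–8) is available and returns the raw score
  without a group mapping, since no canonical grouping exists for it.

The upgrade sums use *weighted* percentages, consistent with the
quantification model. The threshold sweep re-grades a cohort over a grid
of cut-offs and reports group sizes, the log-rank statistic and the
concordance index of the grade as an ordinal predictor; threshold 100
reproduces WHO exactly (no upgrade possible) and threshold 0 upgrades
every lower-grade case with any high-grade pixel — both limits are
asserted in the tests.

## Agreement statistics

Pattern labels are nominal, but confusions concentrate between
morphologically adjacent patterns, so both conventions are shipped:
unweighted Cohen's kappa and an *equal-weight* (linearly spaced) weighted
kappa over a declared category order, defaulting to the severity order.
The weighted variant is the package default for panel reports. Kappa is
defined as 1 in the degenerate case of two constant, identical raters
(chance agreement 1).

Majority vote excludes any declared AI rater — the AI is compared
*against* the human vote, never part of it — and reaches consensus when
the modal label gets at least `consensus_min` votes (default: strict
majority, i.e. 7 of 13). A modal tie never reaches consensus; the
reported vote is then the most severe tied label, flagged. The
leave-one-out analysis removes the target rater (and the AI) from the
vote, restricts to items where the reduced vote still reaches consensus
— consensus-only by default, with the dropped count reported — and
computes kappa and simple agreement between the target and the vote.

## Segmentation evaluation

Per-class Dice, $2|GT_c \cap PR_c| / (|GT_c| + |PR_c|)$, is computed
within the annotated region (ground-truth background/ignore pixels are
excluded first). The summary "average Dice" is the unweighted (macro)
mean over classes present in the ground truth, giving each of the six
patterns equal billing; a support-weighted mean is reported alongside.
The discrepancy matrix row-normalizes the misclassified pixels of each
ground-truth class over the six other patterns plus a seventh
"predicted background" column, so rows sum to 100 when any discrepant
pixel exists and are undefined (NA) otherwise.

## Survival harness

Kaplan–Meier estimation, the k-sample log-rank test and Cox
proportional-hazards fits come from the `survival` package; this module
contributes the grading-to-survival plumbing and encodings. pN2 and pN3
are pooled as one level (2); pT enters ordinal-as-linear by default with
a categorical option; age is linear in years. The grade factor takes the
lowest grade as reference; `grade_coding = "ordinal"` instead fits the
grade rank as a linear term, estimating one per-step log hazard ratio —
the natural scale when hazards are believed to be geometric in grade
steps and the scale on which the synthetic recovery checks are run,
because per-level factor coefficients at realistic cohort sizes carry
standard errors of ~0.1 each and a joint accuracy criterion on them
would measure sampling noise rather than correctness. Missing covariates
are handled complete-case per model, with the used n reported.
Non-convergence or separation flags the affected model instead of
failing the run.

## The synthetic generators

The generators define the standard study conditions and are first-class,
tested code.

* `gen_mask_pair()`: ground truth as Voronoi-like blobs from random seed
  points (default 64 × 64, 25 blobs, 15% background); the prediction
  corrupts each pixel independently through a row-stochastic confusion
  matrix. Confusions built by `make_confusion()` place the off-diagonal
  mass geometrically decaying with severity distance, mimicking
  confusions between adjacent morphologies.
* `gen_rater_panel()`: 283 items, 13 raters by default; a latent pattern
  per item from a prior, each rater's label through their personal
  confusion matrix. Per-rater accuracies 0.55–0.80 emulate low-to-
  moderate agreement. The expected pairwise kappa is available in closed
  form (`expected_pairwise_kappa()`), which turns agreement tests into
  analytic-oracle comparisons.
* `gen_cohort()`: 1000 cases by default over five prognostic groups
  (prior 0.15/0.20/0.25/0.20/0.20, light on the rare lepidic-predominant
  group). Each case gets a dominant/secondary pair whose tiers sum to the
  group's score, a composition with dominant 50–65% and the secondary
  taking 55–70% of the remainder (which guarantees re-grading recovers
  the latent group exactly), exponential survival with a per-step log
  hazard ratio of 0.6 and a baseline rate of 0.01/month, and independent
  exponential censoring calibrated to a 20% expected censored fraction.
  pT, pN and age are drawn with mild positive grade correlation; cohort
  labels C1–C5 support subgroup-filter tests.

What the generators do *not* emulate: spatial correlation of rater
errors, histology texture, informative censoring, cohort-specific
follow-up and case-mix differences, and inter-slide heterogeneity within
a case. Passing tests therefore demonstrate correctness of the rules and
statistics under known sampling models — not clinical performance on
real cohorts, which requires external data.

## Numerical choices and degenerate inputs

* Percentages must sum to 100 within 1 point in table input
  (renormalized; worse sums are an error), and compositions sum to 100
  within 1e-9 internally.
* Dominant/secondary ties: severity order, deterministic; engine and
  brute-force oracle agree on the full 5%-step simplex where ties are
  dense.
* Empty compositions error in grading; all-background masks are flagged,
  not fatal.
* Degenerate sweeps (all cases in one grade group) report NA log-rank
  rather than failing.
* Test problem sizes: the grading oracle runs the full 5%-step simplex
  (53 130 compositions); agreement oracles use 10 000-item panels
  (Monte-Carlo error ~0.01 in kappa); survival recovery uses the
  standard 1000-case cohort and 100 replicate seeds for the ordering
  property.

## Known limitations

Correction weights are treated as universal constants although they were
calibrated on one training distribution; the package exposes them as
parameters. The prognostic-group mapping for the four-tier-scored
variant is intentionally not provided. Proportional-hazards diagnostics
are limited to convergence/separation flags. WSI formats, tissue/tumor
detection and the segmentation model itself are out of scope — the
package consumes label masks.
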