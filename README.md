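# luadgrade

Growth-pattern quantification, grading and prognostic validation for lung
adenocarcinoma (LUAD) histology.

Resectable LUAD is graded from its architectural growth patterns —
lepidic, acinar, papillary, micropapillary, solid and complex glandular
(cribriform / fused glands). Pixel-level semantic segmentation of whole
slide images makes the pattern composition of a tumor fully quantitative,
which raises three practical questions this package addresses:

1. **Quantification.** How much of each pattern does a slide or case
   contain? Raw pixel counts under-represent low-grade patterns, because
   the epithelial tumor component is sparser in lepidic growth than in
   high-grade patterns. Slide areas are therefore multiplied by per-pattern
   correction weights (lepidic 1.41, acinar 1.35, papillary 1.06,
   micropapillary 1.14, solid 1.0, complex glandular 1.10) before
   percentages are formed; multi-slide cases pool weighted areas, not
   slide percentages.
2. **Grading.** Which rule turns a composition into a grade? Five systems
   are implemented as explicit rule engines:
   * **WHO** — dominant pattern only: G1 lepidic, G2 acinar/papillary,
     G3 micropapillary/solid/complex glandular;
   * **IASLC** — WHO base grade, upgraded to G3 when the summed high-grade
     abundance (micropapillary + solid + complex glandular) is strictly
     greater than 20%;
   * **simplified IASLC** — complex glandular removed from the upgrade sum;
   * **modified IASLC** — upgrade threshold raised to 50%;
   * **four-tier** — complex glandular as its own intermediate grade:
     G1 lepidic, G2 acinar/papillary, G3 complex glandular, G4
     micropapillary/solid;
   * **prognostic score** — Gleason-style sum of the dominant and
     secondary pattern tiers, score 3 split into 3a (1 + 2) and 3b (2 + 1),
     mapping to prognostic groups PG1–PG5 (purely lepidic tumors, score 2,
     are reported as PG0).
3. **Validation.** Does a grading separate outcomes? A survival harness
   (Kaplan–Meier curves, k-sample log-rank, uni/multivariate Cox with pT,
   pN and age) stratifies any cohort by any of the systems, including a
   systematic sweep of the IASLC upgrade threshold, and Stage I / pT1
   subgroup filters.

Around these sit a multi-rater agreement suite (equal-weight and
unweighted Cohen's kappa, simple agreement, majority vote with a
≥ 7-of-13 consensus rule, leave-one-out analysis), per-class Dice and
discrepant-pixel evaluation of predicted masks, and seeded synthetic
generators (masks with known confusion, rater panels with known per-rater
confusion matrices, survival cohorts with known proportional-hazards
structure) so every analysis can be exercised against known ground truth.

## Worked example

```r
library(luadgrade)

# a 100 x 100 label mask: 52% acinar, 26% lepidic, 18% solid, 4% background
mask <- label_mask(matrix(c(rep(2L, 5200), rep(1L, 2600), rep(5L, 1800),
                            rep(0L, 400)), 100, 100), "slideA", mpp = 0.5)
sc <- quantify_mask(mask, pattern_codebook(), correction_weights())
sc
#> <slide_composition> slideA
#>         lepidic   acinar papillary micropapillary    solid complex_glandular
#> pixels 2600.000 5200.000         0              0 1800.000                 0
#> area      0.001    0.002         0              0    0.000                 0
#> pct      29.361   56.223         0              0   14.416                 0

cc <- aggregate_case(list(sc), case_id = "patient01")
grade_who(cc)          #> WHO -> G2          (dominant acinar)
grade_iaslc(cc)        #> IASLC -> G2        (14.4% high-grade, not > 20%)
grade_four_tier(cc)    #> FOUR_TIER -> G2
score_prognostic(cc)   #> PROG_SCORE -> PG2  (acinar + lepidic = score 3b)
```

The correction weights shift the percentages toward the sparse patterns:
the 26% lepidic pixels become 29.4% of the weighted tumor area, while the
18% solid pixels drop to 14.4% — which here is what keeps the case below
the IASLC upgrade threshold.

A full synthetic study, from cohort generation to prognostic validation:

```r
co <- gen_cohort(n_cases = 1000, log_hr_step = 0.6, censoring = 0.2, seed = 1)
pg <- grade_cases(co$compositions, "PROG_SCORE")
km <- km_logrank(co$records, pg$grade_label)
km$chisq            # 4-df log-rank chi-square across PG1..PG5
cox_fit(co$records, pg$grade_label, grade_coding = "ordinal")
#   multivariate per-step log hazard ratio ~ 0.6 (the generating value)
```

A thin command-line front end over the same functions ships in
`inst/cli/luadgrade.R` with subcommands `quantify`, `grade`, `sweep`,
`agree`, `segeval`, `survival` and `simulate`.

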