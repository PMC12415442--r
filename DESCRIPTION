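Package: luadgrade
Title: Growth-Pattern Quantification, Grading and Prognostic Validation for
    Lung Adenocarcinoma Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts pixel-level growth-pattern segmentation masks of lung
    adenocarcinoma (lepidic, acinar, papillary, micropapillary, solid,
    complex glandular) into correction-weighted slide- and case-level
    pattern compositions, and grades each case under five competing
    systems: WHO three-tier, IASLC with high-grade upgrade, a simplified
    and a modified IASLC variant, a four-tier dominant-pattern grading,
    and a Gleason-style dominant-plus-secondary prognostic score with a
    3a/3b split. Ships a multi-rater agreement suite (equal-weight and
    unweighted kappa, simple agreement, majority vote with consensus
    rule, leave-one-out analysis), per-class Dice and discrepant-pixel
    evaluation of segmentation masks, a Kaplan-Meier / Cox validation
    harness, and fully seeded synthetic generators for masks, rater
    panels and survival cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
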