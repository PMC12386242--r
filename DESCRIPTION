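Package: heartperm
Title: Scoring and Permutation Inference for Cardiac Cell-Division
    Defects in the Drosophila Embryonic Heart Tube
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying cardiac progenitor cell-division
    defects scored from the Drosophila melanogaster embryonic dorsal
    vessel (heart tube). Converts per-hemisegment Tinman and Seven-up
    lineage cell counts into a three-category defect classification
    (Tin-lineage symmetric, Svp-lineage earlier-superprogenitor, and
    Svp-lineage asymmetric division errors), aggregates defect
    proportions per embryo and per genotype, and performs permutation
    (randomization) inference on the embryo-level proportions: a
    two-group comparison of defect rates and a genetic-interaction
    (synergy) test for double heterozygotes based on a no-intercept
    interaction model with Smith orthogonalization of the interaction
    regressor. Includes a synthetic-cohort generator with embryo-level
    correlated defect probabilities for power and calibration studies,
    and an end-to-end pipeline producing per-genotype report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
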