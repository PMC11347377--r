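Package: adipoquant
Title: MRI-Based Adipose Tissue Volumetrics and Weight-Loss Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies abdominopelvic adipose tissue from proton density fat
    fraction (PDFF) maps and subcutaneous/visceral (SAT/VAT) label masks:
    depot volumes, mean PDFF, apparent lipid volumes, craniocaudal
    equidistant-thirds subdivision and length-normalized volumes; derives
    absolute and relative changes between two timepoints; and provides the
    cohort statistics layer used in weight-loss imaging studies (paired and
    independent t-tests, standardized mean differences with paired-design
    confidence intervals, correlation screening, and stepwise multiple linear
    regression with p-value entry/removal rules). Includes seeded generators
    for 3D PDFF/mask phantoms with analytic ground truth and for tabular
    synthetic cohorts with planted regression structure, so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
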