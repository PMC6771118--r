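Package: bestqspr
Title: Quantitative Structure-Pathogenicity Modelling of BEST1 Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative structure-pathogenicity analysis of
    missense variants in bestrophin-1 (BEST1), the protein whose pentameric
    assembly forms the calcium-activated chloride channel of the retinal
    pigment epithelium. Implements the age-adjusted Best's Disease Severity
    Index (BDSI) computed from per-eye logMAR visual acuities, the relative
    dimerization and calcium-binding energy algebra over molecular-mechanics
    totals, a linear BDSI-versus-|ddE_dim| regression with leave-one-out
    cross-validation and iterative outlier removal, and the predicted mean
    visual acuity (PMVA) pathogenicity classifier. Ships the source proband
    cohort and per-variant energy tables as plain-text fixtures, a seeded
    synthetic-cohort generator for validation studies, and a reduced-scope
    residue-location annotator for multimeric channel structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
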