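Package: ductdose
Title: Parotid Duct Dose Constraints for Patient-Reported Xerostomia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying organ-at-risk mean-dose constraints that
    stratify patient-reported xerostomia after head-and-neck radiotherapy,
    with a focus on the parotid ducts. Implements outcome dichotomization of
    PRO-CTCAE dry-mouth scores, a maximally separating cut-point search over
    a 1 Gy grid using one-sided Fisher exact tests with a minimum group-size
    constraint, Monte-Carlo propagation of Gaussian surrogate-dose error
    through constraint classification (with a closed-form sensitivity and
    specificity oracle), contour agreement metrics (mean distance to
    agreement, dose-difference statistics), cohort-comparison tests, and a
    synthetic-cohort generator so every stage of the pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
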