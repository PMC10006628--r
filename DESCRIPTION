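Package: somastrat
Title: Proteomic Risk Stratification for Heart Failure After Myocardial
    Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for aptamer-based (SOMAscan-style) proteomic
    risk stratification of myocardial-infarction patients: raw-signal
    normalization and calibration with QC acceptance reporting, SOMAmer-level
    cleanup and protein aggregation, derivation-cohort-anchored
    standardization, per-protein Fine-Gray subdistribution-hazard screening
    with Bonferroni familywise error control, silhouette-selected k-means
    patient stratification transferred to a validation cohort by
    nearest-centroid assignment, group-level competing-risk prediction, and
    Fisher-exact overrepresentation of the selected panel in user-supplied
    term sets. Includes a synthetic-cohort generator emulating plate-structured
    relative-fluorescence data and competing-risk outcomes so the whole
    workflow is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cmprsk,
    cluster,
    mclust
Config/testthat/edition: 3
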