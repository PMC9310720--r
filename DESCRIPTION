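Package: mddburden
Title: Registry-Based Burden Analysis of Incident Major Depressive Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for estimating the clinical and societal burden
    of incident major depressive disorder (MDD) from registry-shaped event
    tables (diagnoses, drug dispensations, procedures, outpatient visits,
    inpatient stays, and work-loss spells). Provides a configurable ICD-10/ATC
    codebook, incident-cohort construction with matched controls sampled with
    replacement, stitching of dispensation and diagnosis streams into MDD
    treatment episodes with a maximum-gap rule and supply-based extension,
    monthly treatment-exposure and comorbidity trajectories, follow-up-weighted
    annual burden estimates with robust (sandwich) standard errors,
    Kaplan-Meier episode duration, an in-package Cox proportional-hazards fit
    for all-cause mortality, and care-level referral flow tables. A synthetic
    registry generator with per-person hashed random substreams supplies
    ground-truth data at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
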