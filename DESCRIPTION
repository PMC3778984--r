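Package: fcrkit
Title: Corticospinal Functional Connectivity Ratios from TMS Recruitment
    Curves, with Diffusion-MRI Asymmetry and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the balance of ipsilateral versus contralateral
    corticospinal control of the lower limb after stroke. Motor evoked
    potentials in rectified surface EMG are reduced to windowed burst areas,
    normalized to pre-trigger activity, and fitted as linear recruitment
    curves over stimulation intensity; the ratio of ipsilateral to
    contralateral slopes gives a functional connectivity ratio (FCR) per leg.
    Companion tools compute region-of-interest fractional-anisotropy
    asymmetry of the internal capsule, lesion volume, and lesion overlap with
    a corticospinal-tract probability map from NIfTI volumes, and run the
    cohort correlation battery (tie-aware Spearman rank correlation, paired
    t, 2x2 within-subject ANOVA, capped multiplicity correction, forward
    stepwise regression). A synthetic-cohort generator emulates EMG sessions,
    FA phantoms, and behavioral scores with a latent severity gradient so the
    full pipeline is testable end to end, and a published 13-patient
    reference cohort is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
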