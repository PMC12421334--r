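Package: clbpmca
Title: Sex-Stratified Biopsychosocial Phenotyping of Chronic Low Back Pain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-usable pipeline for biopsychosocial phenotyping of chronic
    low back pain (cLBP) in working populations. Questionnaire variables
    (BPI, DN4, HADS, PCS, TSK, FABQ, SF-12, stress scales) are categorized
    into ordered modalities per sex (referenced cut-offs, terciles, or
    density-valley cut-offs), analysed by Multiple Correspondence Analysis
    with Benzecri-adjusted inertia rates, and the modality coordinates are
    clustered by three methods in parallel (Ward hierarchical, k-means,
    optimal univariate partitioning); the consensus cluster anchored on the
    highest pain-interference modality summarizes the worst cLBP state.
    Includes derived-variable rules (BMI classes, DN4-based pain-type
    adjudication, eligibility filtering), a descriptive/comparative
    statistics layer with explicit test-selection rules, and a seeded
    synthetic-cohort generator with a latent disorder factor for fully
    reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
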