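Package: glymkit
Title: Glymphatic MRI Markers: Perivascular Space Burden and the DTI-ALPS Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies two non-invasive MRI markers of glymphatic function:
    enlarged perivascular space (ePVS) burden segmented from co-registered
    T1-weighted and T2-weighted volumes via an enhanced perivascular contrast
    image and multiscale Frangi vesselness filtering, and the DTI-ALPS
    (diffusion along the perivascular space) index computed from diffusion
    and kurtosis tensor fits of two-shell diffusion MRI. Ships synthetic
    structural and diffusion phantom generators with analytic ground truth,
    a synthetic two-visit cohort simulator, and the accompanying statistical
    battery (group tests, age and symptom associations, linear mixed models
    for visit effects, longitudinal ratio correlations, stepwise logistic
    prediction with bootstrap ROC/AUC comparison, and FDR correction), so the
    whole pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
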