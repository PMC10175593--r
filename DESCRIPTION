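Package: midfuse
Title: Mid-Level Data Fusion of Multi-Sensor Panels for Herbal Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric toolkit for authenticating and classifying herbal
    samples from heterogeneous instrument blocks (electronic nose, electronic
    tongue, electronic eye, near-infrared spectra). Provides NIPALS partial
    least squares discriminant analysis with variable importance in projection
    (VIP) selection, principal-component discriminant analysis (PCA-DA) with
    Wilks' lambda backward elimination, competitive adaptive reweighted
    sampling (CARS) for wavelength selection, mid-level feature fusion,
    leave-one-out cross-validated evaluation (confusion matrices,
    sensitivity/specificity/precision/accuracy, ROC/AUC), and a synthetic
    multi-sensor panel generator with planted ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
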