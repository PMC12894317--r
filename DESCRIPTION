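Package: periskin
Title: Periorbital Skin Age from Image-Derived Aging Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies periorbital (eye-region) skin aging from facial image
    patches and landmark geometry, and turns the resulting indices into a
    biological-age biomarker. Provides a synthetic-data module (image patches
    with ground-truth wrinkles, spots and landmarks; cohort tables with a
    configurable feature-age correlation structure), a Hessian-eigenvalue
    ridge detector with FFT-based enhancement for wrinkle scoring, a blob
    detector for pigmented-spot scoring, landmark-based morphology indices
    (eye droopiness, temporal width), an ensemble of nine linear
    age-prediction models evaluated by 10-fold cross-validation and refined
    by removal of negative coefficients, and logistic disease-association
    analyses with Benjamini-Hochberg false-discovery-rate control and PCA of
    disease-history indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
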