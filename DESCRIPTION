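Package: cardiosex
Title: Sex-Specific Drug-Induced Arrhythmogenesis Modeling and Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex- and layer-specific human ventricular cardiomyocyte simulation
    (a modified O'Hara-Rudy model with the ten Tusscher fast sodium current),
    Hill-equation ion-channel drug block, Latin-hypercube sensitivity screening
    of de- and repolarization abnormalities with logistic-regression marginal
    effects, a one-dimensional transmural-cable monodomain surrogate with
    pseudo-electrocardiograms, single- and multi-fidelity Gaussian-process
    arrhythmogenicity classifiers with active learning, and critical
    drug-concentration risk stratification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    lhs,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
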