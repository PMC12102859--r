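Package: auriscreen
Title: Automated Screening of Ear Lesions in Slaughtered Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting ear-biting lesions on pig carcass
    photographs taken along the slaughter line. Standardizes raw images,
    segments the carcass, isolates the two auricles, and classifies each
    ear with a two-stage cascade of small convolutional neural networks
    into healthy, lesion, or slaughter artefact. Includes 3-class
    screening metrics (accuracy, sensitivity, specificity under a
    healthy-versus-defect binarization), Cohen's kappa and multi-rater
    unanimity accounting, plus a seeded synthetic carcass-image generator
    and simulated raters so the whole pipeline is testable without real
    abattoir data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    png,
    EBImage,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
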