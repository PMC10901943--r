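Package: stainshift
Title: Stain Normalization, Artifact Injection and NoisyEnsemble Planning
    for Cross-Institution Histopathology Tile Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and improving how well histopathology tile
    classifiers transfer between institutions. Implements Beer-Lambert
    optical-density conversion and Vahadane-style stain normalization via
    sparse two-stain matrix factorization, HSV color augmentation,
    parameterized scanner-artifact injectors (Gaussian blur, JPEG
    compression, brightness, contrast), patient-stratified cohort handling,
    bagging and NoisyEnsemble training plans with single-class-per-patient
    label flips, and an internal-versus-external evaluation harness with
    paired-seed experiment protocols. Ships a deterministic synthetic
    generator of two-stain H&E-like tiles whose class signal is
    morphological and whose domain signal is purely colorimetric, so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jpeg,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
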