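Package: mkdarf
Title: Multi-Kernel Domain Adaptation and Random Forest Decoding for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-subject and cross-session decoding of two-class motor-imagery
    EEG with an emphasis on low-performing ("BCI-illiterate") users. Implements
    a multi-kernel extreme learning machine (MK-ELM) that learns a weighted
    combination of polynomial, Gaussian and wavelet kernels on labeled source
    trials, aligns source and target feature distributions in the induced
    kernel space by minimizing the multi-kernel maximum mean discrepancy
    (MK-MMD) through a regularized trace eigenproblem, and classifies the
    adapted features with a random forest. Includes the standard common
    spatial pattern (CSP) log-variance front end (band-pass, downsample,
    epoch crop, spatial filtering) and a synthetic motor-imagery EEG generator
    with controllable event-related desynchronization depth and source-to-target
    domain shift, so the complete pipeline is testable without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
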