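Package: mitrainr
Title: Trial-Feedback Motor-Imagery Training and Decoding for EEG-Based
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for running and evaluating a two-class motor-imagery
    (MI) brain-computer interface training protocol with per-trial
    neurofeedback. Implements ERD/ERS topographic scoring of single
    trials with a qualitative 'good'/'fight' verdict, EOG-based blink
    gating of distracted trials, iterative variance-based artifact
    rejection, Riemannian-aligned common spatial pattern (CSP) feature
    extraction with linear discriminant analysis (LDA) decoding, and
    run-level evaluation via class-distance and cross-validated
    accuracy. A synthetic EEG/EOG session generator with lateralized
    mu-rhythm modulation makes the whole pipeline testable without
    recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
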