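Package: wmload
Title: Decoding Working-Memory Load from Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for analysing load-dependent neural
    activity in trial-epoched intracranial EEG from the hippocampus,
    entorhinal cortex, and lateral temporal cortex. Provides Morlet
    time-frequency decomposition with bootstrap baseline z-scoring,
    single-regional, cross-regional and residual-based linear SVM decoding
    of working-memory load with permutation statistics, phase-locking-value
    connectivity with repeated-measures load ANOVAs, behavioural capacity
    metrics (Pashler's K), and a synthetic multi-subject recording
    generator with controllable load effects, hub-shared latent activity
    and von Mises phase coupling for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    arrow,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
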