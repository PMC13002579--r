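Package: stschair
Title: Mapping Sit-to-Stand Muscle Activity to Assistive-Chair Control Variables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Offline analysis pipeline linking surface-EMG muscle activity
    recorded during sit-to-stand (STS) motion to the four binary control
    variables of a two-degree-of-freedom assistive chair. Provides a synthetic
    STS trial generator, EMG activation-envelope extraction (40-400 Hz
    band-pass, rectification, 4 Hz low-pass, fourth-order zero-phase
    Butterworth), phase segmentation from trunk tilt and seat reaction force,
    a 100-dimensional per-trial feature protocol, L1-regularized logistic
    classifiers for each control variable with class-separability scoring,
    and a prototype-based inverse evaluation that compares
    classifier-inferred muscle-activity prototypes against all non-target
    control combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    signal,
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
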