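Package: emgh
Title: Hierarchical Classification of Hand/Wrist Gestures and Grasp Force
    from Enveloped Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pattern-recognition myoelectric control research:
    sliding-window time-domain feature extraction (EMAV, EWL, SSC, RMS, VAR)
    from multi-channel enveloped surface electromyography, one-vs-all
    logistic regression (linear and polynomial), linear discriminant
    analysis, and a hierarchical gesture-to-force cascade that classifies
    seven hand/wrist gestures and, for the two grasp classes, three force
    levels. Includes dynamometer-based force-threshold calibration,
    prosthesis command mapping, a synthetic enveloped-EMG session generator
    for protocol-faithful experiments without subject data, offline
    evaluation (accuracy, per-class F1, confusion matrices, Mann-Whitney U
    with Bonferroni correction), and a simulated real-time decision stream
    with online accuracy and motion completion rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
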