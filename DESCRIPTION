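Package: p53screen
Title: Analysis of Arrayed RNAi Screens for Regulators of p53-Dependent Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for chromatin-focused siRNA screens
    read out by RT-qPCR against p53 target genes. Implements relative
    standard curve quantification of Ct values, reference-gene (LMNA)
    normalization, z-score hit calling with configurable thresholds,
    classification of joint and readout-specific regulators across two
    treatment conditions, secondary-screen validation with false-positive
    flagging, screen quality control (Z'-factor and control-versus-average
    t-tests), and a from-scratch Kohonen self-organizing map for clustering
    expression profiles. A seeded synthetic-screen generator with planted
    regulator effects makes every pipeline stage verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
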