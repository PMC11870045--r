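Package: ephystype
Title: Electrophysiological Typing and Pharmacology Analysis of Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of whole-cell current-clamp recordings from
    cortical interneurons: per-sweep spike and passive-property feature
    extraction, Hill-sigmoid characterization of firing-frequency versus
    injected-current (F-I) curves, Ward hierarchical clustering of cells into
    electrophysiological types with random-forest feature importance and PCA
    factor maps, scaled-template detection of spontaneous synaptic currents,
    and normality-gated statistical comparison of drug conditions. A
    parametric adaptive exponential integrate-and-fire simulator with a
    stereotyped spike waveform generates ground-truth recordings emulating
    square-pulse step families, sag/test pulses and gap-free traces, so the
    whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    minpack.lm,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
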