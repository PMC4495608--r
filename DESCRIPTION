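Package: ssepmap
Title: Topographic Microstate and Source Analysis of Somatosensory Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for whole-scalp somatosensory evoked
    potential (SSEP) analysis in anaesthetized macaques: evoked-potential
    preprocessing (band-pass filtering, artifact rejection, averaging,
    baseline correction, average re-referencing), topographic microstate
    segmentation by modified K-means clustering with Krzanowski-Lai and
    cross-validation model selection, template back-fitting with eight
    topographic parameters and pre/post group statistics, classical
    component analysis, and a LORETA-style distributed inverse solution on
    a three-shell spherical head model. A forward simulator with known
    microstate scripts, dipole sources and noise provides ground-truth
    data so every stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    Matrix,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
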