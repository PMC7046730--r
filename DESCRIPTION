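Package: vasrf
Title: Virtual Auditory Space Stimuli and Spatial Receptive Field Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how sound-localization cues shape auditory
    spatial receptive fields. Reconstructs head-related impulse responses
    (HRIRs) from complementary Golay-code measurements, extracts interaural
    time and level differences and spectral cues from HRIR grids, and
    synthesizes virtual auditory space stimuli in which individual cues are
    frozen at a reference value. Includes a parametric mouse-like HRTF
    generator and an overdispersed spiking-neuron simulator with known
    receptive-field structure, quasi-Poisson response significance tests,
    maximum-quasi-likelihood Kent-distribution receptive-field fits with BIC
    model selection, topographic-map regression with systematic errors,
    cosine similarity indices for cue-freezing experiments, and binaural
    spectro-temporal receptive fields estimated by spike-triggered averaging
    of dynamic random chord stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
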