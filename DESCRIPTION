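Package: emonirs
Title: Vocal-Emotion Prosody Manipulation and fNIRS Block-Design Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying cortical responses to vocal emotion with
    functional near-infrared spectroscopy (fNIRS). Provides prosody-cue
    attenuation of speech stimuli (fundamental-frequency flattening by
    pitch-synchronous overlap-add, frame-wise intensity equalisation, and
    pitch-preserving time-scale modification), 4-AFC and block-design trial
    scheduling, a forward simulator of dual-wavelength fNIRS recordings with
    systemic physiology and short-separation channels, a first-level GLM
    (optical density, modified Beer-Lambert law, canonical HRF design,
    short-channel principal-component nuisance regression, AR(1)
    prewhitening, SE-weighted region-of-interest pooling), and second-level
    mixed-model contrasts with Benjamini-Hochberg FDR, Cook's-distance
    screening, Nakagawa R2, confusion-matrix and brain-behaviour analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
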