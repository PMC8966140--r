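Package: selfmotion
Title: Self-Motion Analysis and Hearing-Aid Acoustic Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for listener self-motion in virtual acoustic
    environments and its acoustic consequences for hearing-aid processing.
    Ingests head/torso tracking and electrooculogram (EOG) streams, corrects
    EOG drift, fuses head and eye rotations into gaze at a common sampling
    rate, detects saccades, and computes movement measures (GazeStd, HeadStd,
    speeds, gaze-jump rate, HeadGazeRatio, target-tracking RMS errors).
    Renders multi-talker scenes to a 29-direction virtual loudspeaker layout,
    applies measured head motion to the receiver, and convolves with a
    parametric head/hearing-aid impulse-response model to obtain 4-channel
    hearing-aid microphone signals separately for target and noise. Includes
    a two-microphone adaptive differential microphone (ADM) with shadow
    processing of clean components, better-ear segmental SNR estimation
    (SNRrelative, SNRimprovementADM), a seeded synthetic behaviour-and-scene
    generator, and repeated-measures group statistics (mixed ANOVA with
    Greenhouse-Geisser correction, Benjamini-Hochberg and Bonferroni
    adjustments).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
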