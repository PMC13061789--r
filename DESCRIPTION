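Package: multitact
Title: Simulation and Timing Analysis Tools for Browser-Based Multisensory
    Reaction-Time Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for planning and analysing remote multisensory
    reaction-time experiments that deliver visual, auditory and vibrotactile
    stimuli through a smartphone browser. Provides a LATER-model Monte Carlo
    power analysis with stimulus-onset jitter, a one-up-one-down adaptive
    staircase for perceptual intensity matching with a simulated-observer
    harness, a redundant-target-effect analysis pipeline (reaction-time
    filtering, repeated-measures ANOVA with Greenhouse-Geisser correction and
    Holm-adjusted pairwise comparisons), and waveform-based stimulus-timing
    analysis (RMS envelope onset detection, trigger-to-onset lag and
    cross-modal asynchrony tables, ramp regression). Every analysis stage is
    paired with a seeded synthetic-data generator that returns ground truth,
    so the full pipeline can be exercised and validated without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
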