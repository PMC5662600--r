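Package: ieegpac
Title: Phase-Amplitude Coupling and Stimulation Entrainment Analysis for
    Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether low-frequency transcranial electric or
    acoustic stimulation entrains sleep rhythms in intracranial EEG
    recordings. Provides complex Morlet band decomposition into
    instantaneous amplitude and phase, harmonic modeling and subtraction of
    sinusoidal stimulation artifacts, cycle-wise phase-amplitude coupling
    with the unnormalized modulation index, phase-randomization surrogate
    significance testing with false-discovery-rate control, sleep spindle
    and slow-wave event detection, spindle-gamma amplitude
    cross-correlation, post-stimulation phase-coherence analysis, projected
    electric-field estimation between adjacent electrodes, and a synthetic
    sleep-iEEG generator with known ground truth for validating the whole
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
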