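Package: pupwake
Title: Arousal-State Transitions and Sensory-Evoked Hemodynamics in Developing Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel recordings of cortical
    hemodynamics (total-hemoglobin changes from intrinsic optical signal
    imaging), nuchal EMG, hippocampal LFP and locomotion in head-fixed
    neonatal and adult mice.  Converts reflectance to hemoglobin
    concentration via the modified Beer-Lambert law, scores arousal state
    in 5-second bins from EMG tone, LFP band power and locomotion,
    extracts qualified sleep-wake transitions and their peri-transition
    blood-volume changes, computes stimulus-evoked response metrics split
    by pre-stimulus arousal state, and fits 1/f power-law models to
    resting-state hemodynamic spectra with pre-whitened vasomotion peak
    detection.  Includes a seeded synthetic-session generator with known
    ground truth (semi-Markov arousal sequences, state-dependent channel
    statistics, gamma-variate evoked responses, stimulus-triggered
    awakening) so every analysis stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
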