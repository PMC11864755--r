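Package: pingCTF
Title: Reconstructing Hidden Spatial Attentional Priority from Alpha-Band
    EEG with Inverted Encoding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for reconstructing spatial attentional
    priority maps from multichannel oscillatory EEG signals using an
    inverted encoding model (IEM) over eight circular locations. Separates
    phase-locked (evoked) from non-phase-locked (total) alpha-band power
    via Butterworth filtering and the Hilbert analytic signal, estimates
    channel tuning functions (CTFs) with partitioned training/testing and
    cross-session generalization, quantifies spatial selectivity with CTF
    slopes, performs cluster-based sign-flip permutation inference, and
    fits distance gradients around a high-probability distractor location.
    Includes a forward-model simulator that generates trial designs,
    behavioral outcomes, and location-tuned multichannel epochs with known
    ground truth for parameter-recovery testing, plus artifact-rejection
    procedures (muscle-band z-score screening with iterative electrode
    interpolation, gaze/HEOG eye-movement rejection) and the accompanying
    behavioral analyses (RT trimming, condition categorization, distance
    ANOVA with Greenhouse-Geisser correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
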