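Package: fpvstag
Title: Frequency-Tagging EEG Analysis for Fast Periodic Visual Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a complete frequency-tagging analysis pipeline for
    steady-state visual evoked potential (SSVEP) experiments in which two
    superimposed stimulus streams are tagged at distinct presentation rates
    (e.g. faces at 6 Hz and houses at 7.5 Hz). Provides a synthetic
    steady-state EEG cohort generator with known ground truth; sequence-locked
    preprocessing (Butterworth band-pass, resampling, bad-channel
    interpolation, common average reference); high-resolution amplitude
    spectra with signal-to-noise ratio, baseline-corrected amplitude and
    z-score statistics based on local noise neighbourhoods; data-driven
    harmonic selection and region-of-interest harmonic summation with
    individual-subject significance; and group-level linear mixed-effects
    modelling with Tukey-corrected post-hoc contrasts, response time-course
    analysis, behavioural summaries and brain-behaviour rank correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
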