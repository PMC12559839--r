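Package: speechersp
Title: Event-Related Spectral Perturbation Analysis of Thalamic Local Field
    Potentials During Speech Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing intracranial local field potentials (LFP)
    recorded from deep brain stimulation lead contacts during speech motor
    tasks of graded complexity (vowel vocalization, diadochokinesis,
    sentence repetition). Provides a synthetic cohort generator (1/f
    background with event-locked, task-graded band-limited power
    modulations), a preprocessing chain (resampling, line-noise notch,
    segmented-contact averaging, common average rereferencing, band-pass
    filtering, onset-locked epoching), per-trial complex Morlet wavelet
    decomposition with decibel baseline normalization, shuffled-baseline
    surrogate significance maps for single conditions and condition
    contrasts, and linear mixed-effects modelling of delta/theta and beta
    band power with Satterthwaite Type III tests and Bonferroni-corrected
    follow-up contrasts.
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
    yaml,
    withr,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
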