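Package: ssepml
Title: Modeling Anesthetic Effects on Somatosensory Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and machine-learning analysis pipeline for quantifying
    the effect of end-tidal sevoflurane concentration on somatosensory
    evoked potential (SSEP) waveforms recorded during intraoperative
    neuromonitoring. Provides a seeded synthetic-session generator with
    dose-dependent amplitude attenuation and latency prolongation of the
    named evoked components (N20/P30, N13/P14, P37/N45), a JSON/CSV session
    data model with anesthesia-timepoint synchronization, five-category
    waveform feature extraction (phase-space curve area, evoked latencies
    and amplitudes, time-frequency peaks, principal-component scores),
    interquartile-range normalization, minimum-redundancy maximum-relevance
    feature ranking, and a ten-preset regression bank (linear model,
    fine/medium/coarse trees, linear/quadratic/cubic support-vector
    machines, narrow/medium/wide neural networks) evaluated by five-fold
    cross-validation and patient-level holdout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    signal,
    e1071,
    rpart,
    nnet,
    withr
Suggests: testthat (>= 3.0.0), pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
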