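Package: epivent
Title: Event Detection in Chronic EEG and Diaphragm EMG Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of chronic dual-channel biopotential telemetry from
    rodent epilepsy models. Conditions raw diaphragm EMG (60 Hz high-pass,
    rectify-and-integrate) and segments it into inspiratory bursts with
    per-breath metrics; classifies spontaneous apneas, sighs and post-sigh
    apneas against trailing same-state baselines; detects electrographic
    seizures, measures postictal generalized EEG suppression (PGES), and
    identifies the transition to persistent epileptiform activity (PEA);
    scores sleep/wake state in 10 s epochs from EEG band power; stages
    disease progression by daily seizure count; and orders terminal events
    (last breath, last heartbeat, EEG power collapse). A deterministic
    synthetic-recording generator with a fully programmed event schedule
    provides ground truth for validating every detector.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
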