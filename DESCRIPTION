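Package: contextstop
Title: Simulation and Analysis of Contextual Stop-Signal Experiments with
    EEG-Informed fMRI Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analysing stop-signal experiments in
    which the behavioural relevance of infrequent stimuli changes with the
    stimulus-response context. Generates context-blocked task schedules with
    adaptive stop-signal delay tracking, simulates trial-by-trial behaviour
    under the independent horse-race model of response inhibition, computes
    the standard behavioural statistics including integration-method SSRT,
    synthesizes stimulus-locked EEG epochs with calibrated band-limited power
    effects and extracts event-related spectral perturbation (ERSP) features,
    and builds and fits first-level fMRI general linear models whose event
    amplitudes are parametrically modulated by single-trial EEG band power.
    All generators are seed-reproducible so that estimator properties can be
    checked by parameter recovery on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
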