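Package: hemowave
Title: Cerebrovascular and Large-Artery Haemodynamic Waveform Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pulse-wave and cerebrovascular haemodynamic analysis:
    calibration of tonometric pressure waveforms to cuff pressures, beat
    detection and ensemble averaging, carotid-femoral pulse wave velocity by
    intersecting-tangent foot detection, beta-stiffness, time-domain
    characteristic impedance, forward/backward wave separation with the
    reflection index, transcranial and carotid Doppler pulsatility, resistive
    and conductance indices, breath-hold cerebrovascular reactivity, and a
    two-group by three-time repeated-measures ANOVA pipeline with partial eta
    squared and Bonferroni post hoc tests. Includes synthetic generators
    (three-element Windkessel pressure/flow, delayed waveform pairs, Doppler
    envelopes, paced-breathing breath-hold sessions, and correlated cohorts)
    with known ground truth so every analysis stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
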