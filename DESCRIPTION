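Package: workhrr
Title: Aerobic Workload from Continuous Workplace Heart Rate Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives individual relative aerobic workload from beat-level
    wearable heart-rate recordings collected over consecutive work days.
    Provides quality control of inter-beat intervals (physiological range,
    neighbour-deviation and beat-error rules), 4 Hz resampling with diary-based
    splitting into work, leisure and sleep periods, heart-rate-reserve outcomes
    (Karvonen percentage of heart rate reserve with the Tanaka age-predicted
    maximum), submaximal cycle-ergometer estimation of maximal oxygen uptake
    (Astrand-Ryhming), and compositional (isometric log-ratio) regression of
    the work-time composition above versus below a workload cut-off, including
    age-interaction and stratified analyses. A calibrated synthetic cohort
    generator supports validation of the whole pipeline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
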