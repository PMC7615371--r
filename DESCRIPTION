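Package: slowbeats
Title: Cortico-Cardiac Coupling Analysis of ECG and EEG Under Propofol
    Anesthesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how anesthetic drugs change the heart rate
    and how cortical slow waves couple to individual heartbeats. Implements
    adaptive R-peak detection with R-wave amplitude tracking, time- and
    frequency-domain heart-rate variability in 5-minute segments,
    slow-wave detection by amplitude and duration criteria on band-limited
    EEG, the RS-interval proportional Shannon entropy statistic with
    uniform-surrogate calibration, heartbeat-locked signal averaging, a
    mixed-effects heart-rate model for clinical drug-concentration tables,
    and a synthetic coupled ECG/EEG generator with known ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    lme4,
    lmerTest,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
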