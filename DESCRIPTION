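Package: ccpulse
Title: Accelerometer-Based Spontaneous Pulse Detection During CPR Pauses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the presence of a spontaneous pulse during chest-compression
    pauses in cardiopulmonary resuscitation (CPR) from the acceleration signal of
    an accelerometer-based CPR feedback sensor. Compression-free 3-second windows
    are located from the acceleration envelope, ECG and acceleration channels are
    band-pass filtered with Butterworth filters, and the peak of the normalized
    cross-correlation between the two (CCp) is used to discriminate perfusing
    rhythm (PR) from pulseless electrical activity (PEA). Includes segment
    annotation from arterial blood pressure (systolic pressure, pulse pressure,
    mean arterial pressure) and a QRS detector, threshold optimization on a
    training split, ROC/AUC evaluation with DeLong comparison of paired AUCs,
    and a seeded generator of porcine-CPR-like multichannel recordings for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
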