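Package: gaitpartition
Title: Few-Shot Hint-Driven Gait Partitioning from Wearable and Laboratory Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions gait recordings into stance and swing phases from foot
    or shank accelerometer signals using a few user-annotated swing-interval
    "hints" and fuzzy time-domain template matching, with an escalation loop
    that requests new hints when partitioning error exceeds an acceptability
    bound. Includes force-plate ground-truth event detection (10 N threshold),
    spatio-temporal gait parameters (step length, gait speed, step counts),
    EMG linear envelopes and time-normalized per-cycle activity curves,
    Kolmogorov-Zurbenko and FFT signal conditioning, an HMM-based unsupervised
    first-pass segmenter, and a synthetic multimodal gait-recording generator
    with exact ground-truth events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    signal,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
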