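Package: dyadcoord
Title: Movement Coordination Analysis for Dyadic Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying interpersonal movement coordination in
    dyadic conversations from pose-keypoint time series. Reads OpenPose-style
    keypoint JSON or flat CSV tracks, cleans them (missing-value exclusion,
    linear interpolation, running median filtering), computes body-scale
    normalised head-mobility measures, and quantifies coordination of
    head-movement direction between the two partners with cross-recurrence
    quantification analysis (time-delay embedding, fixed-recurrence-rate
    thresholding, diagonal and vertical line statistics DET, ENTR, L, Lmax,
    LAM, TT). Includes mixed-effects condition contrasts, a configurable
    synthetic dyad generator with controllable coupling, transmission latency,
    jitter and gesture exaggeration, and an end-to-end pipeline runner.
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
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
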