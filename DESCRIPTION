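Package: eggcircuit
Title: Quantification of Calcium Activity and Behavior in the C. elegans
    Egg-Laying Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for ratiometric GCaMP/mCherry calcium
    imaging of the Caenorhabditis elegans egg-laying circuit in behaving
    animals. Extracts area-adjusted two-channel fluorescence ratio traces
    from image stacks, detects calcium transients (peak amplitude, width at
    half-maximum) from delta-R/R traces, segments recordings into egg-laying
    active and inactive behavior states from egg-release event times,
    quantifies active-state rhythmicity by FFT and Lomb-Scargle periodograms
    in the 0-250 mHz band, assigns a locomotor body-bend phase to each
    transient from flanking ventral-contraction/relaxation landmarks, and
    aligns traces, muscle size and locomotion speed to the moment of egg
    release. Includes a ground-truthed synthetic-recording generator that
    emulates the circuit's statistical structure (alternating behavior
    states, cell-specific rhythmic transient trains, phase-locked vulval
    muscle twitches, egg-release coupling) so every stage is testable
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
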