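Package: respfmri
Title: Breathing Patterns and Their Signatures in Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of two spontaneous breathing
    patterns -- isolated deep breaths (sighs) and slow tapering bursts
    resembling periodic breathing -- in resting-state fMRI sessions with
    concurrent respiratory-belt and pulse-oximetry recordings. Provides
    cleaning of 400 Hz physiological traces, the standard respiratory
    measures (sliding-RMS envelope, respiration variance, respiration
    volume per time), pulse peak detection and heart rate, fMRI quality
    series (DVARS, framewise displacement in original, respiration-filtered
    and 4-TR variants), carpet-plot rendering, an automated pattern index
    combining respiratory-trace priors with template fits to the global
    fMRI signal, event-locked analyses, global and parcelwise functional
    connectivity with permutation inference, cohort-level statistics, and a
    ground-truthed synthetic-data generator so the full pipeline runs and
    is testable without any external download.
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
    yaml
Suggests:
    car,
    optparse,
    patchwork,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
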