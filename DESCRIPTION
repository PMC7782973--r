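Package: gaitalpha
Title: Occipital Alpha Power, Eye Movements and Gait Phase from Mobile EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for synchronized mobile EEG, electrooculogram,
    ankle-velocity and pupillometry recordings from overground walking
    sessions. Extracts occipital alpha power via PCA/Infomax ICA with
    rule-based component selection, detects saccades and blinks from the
    EOG, segments stride cycles from combined ankle speed, bins any
    co-registered signal into nine walking phases, and evaluates condition
    and phase effects with randomization (permutation) within-subject ANOVA
    and paired tests under Benjamini-Yekutieli false-discovery-rate control.
    Includes a synthetic-session generator with fully known ground truth so
    every stage of the pipeline can be validated end to end.
License: MIT
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
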