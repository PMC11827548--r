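Package: caninetmr
Title: Canine Sleep EEG Analysis for Targeted Memory Reactivation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for canine targeted-memory-reactivation (TMR)
    sleep studies: 20-s-epoch hypnogram macrostructure variables, stage-
    restricted EEG power spectra with Ruger-area multiple-comparison
    correction, adaptive amplitude-frequency sleep-spindle detection with
    slow/fast classification and density statistics, non-REM-gated cue
    scheduling, and behavioral learning statistics (cueing benefit, relative
    latency reduction). Includes a synthetic polysomnography and behavior
    generator with ground truth so the full pipeline is testable without
    animal data.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
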