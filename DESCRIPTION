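Package: alphalat
Title: Alpha Lateralization and Midfrontal Theta Analysis for Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of hemispheric alpha-band (8-12 Hz)
    lateralization and midfrontal theta (4-6 Hz) power in cued visual-search
    EEG experiments. Provides a synthetic-cohort generator for epoched
    oscillatory EEG with a factorial cue-by-distractor-similarity design,
    adaptive three-cycle Hann time-frequency decomposition with relative
    baseline normalization, hemisphere flip-and-pool sensor mapping,
    spatio-temporal cluster-based permutation tests, within-subject
    behavioral statistics, and a rank correlation linking alpha
    lateralization to reaction-time distractor cost.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    Matrix,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
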