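Package: hypoquant
Title: Quantification of Anti-Correlated Hypothalamic Activity Across Hunger States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying the opposing activity of the caudal
    and lateral hypothalamus of larval zebrafish across hunger states.
    Implements stained-brain pERK quantification (ROI mean fluorescence with
    control normalization, adaptive-threshold active-cell counting, prey-type
    activity-change ratios, and voxelized independent-component activity
    maps), calcium-trace analysis (delta-F/F, quadratic detrending,
    spike detection, spike-triggered averages, voxel cross-correlograms and
    an anti-correlation rank-enrichment statistic), pre/post optogenetic
    window metrics with paired rank statistics, and behavioral statistics
    (posture featurization of swim bouts, binned hunting-bout probabilities
    with exact binomial intervals and per-bin Fisher tests, and
    gut-fluorescence food-intake quantification). A synthetic-data module
    generates every input with ground truth attached so each stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
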