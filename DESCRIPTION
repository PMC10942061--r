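Package: calcitrack
Title: Segmentation, Tracking and Spike Analysis for Calcium Fluorescence Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for intracellular calcium imaging of
    clustered, non-migratory cells (such as pancreatic beta cells): build a
    maximum-value composite across a time-lapse stack, segment it once into a
    static label mask (optionally seeded by a nuclear channel), replicate the
    mask over every frame to extract per-cell intensity tracks, subtract a
    randomly sampled background, normalize each trace to a per-cell baseline,
    call calcium spikes by single-step and cumulative percent-rise rules, and
    summarise trial-level spiking activity with Z-score outlier removal and
    paired pre/post testing. Includes a seeded synthetic-movie generator with
    full ground truth so every stage can be benchmarked without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
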