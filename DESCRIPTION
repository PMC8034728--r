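Package: apoptomap
Title: Spatiotemporal Mapping of Apoptosis in Tumor-on-Chip Time-Lapse Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cancer-cell apoptosis in two-channel time-lapse
    recordings of tumor-on-chip cultures, where cancer cells carry a red
    vital pre-stain and a caspase-3/7 reporter turns green at apoptosis
    onset. Cells are localized per frame by a circular Hough transform on
    the Otsu-binarized red channel and linked into tracks by optimal
    assignment. A background-normalized green trace is extracted per track,
    death times are called by pooled Otsu thresholding of all traces, and
    apoptosis-rate and overall-survival kinetics are derived. Death events
    are then propagated as eroding grayscale wakes, aggregated into
    cumulative maps, and summarized by a pairwise-distance-weighted
    potential of death induction that separates transmissible from random
    cell death; chains of death yield per-cell induction intervals. A
    seeded simulator generates ground-truthed synthetic videos and event
    patterns so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
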