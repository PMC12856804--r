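Package: albatrack
Title: Colony-Level Spatial Segregation and Fisheries Overlap from Seabird Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying at-sea spatial segregation between seabird
    breeding colonies and its consequences for fisheries-overlap risk.
    Provides central-place foraging trip processing (speed filtering,
    regularization to fixed intervals, trip splitting, breeding-stage
    inference, trip summary statistics), kernel utilization distributions
    with 50%/95% isopleths, Bhattacharyya-affinity overlap with a
    trip-randomization segregation test, sample-representativeness
    bootstrapping, circular statistics for wind and departure bearings
    (Watson's two-sample U2 test, von Mises circular-circular and
    circular-linear regression), a grid-based bird-by-fishery overlap
    index disaggregated by gear and flag state, and data preparation for
    habitat models (pseudoabsence generation, covariate transforms,
    collinearity screening, AUC scoring). A seeded synthetic-data
    generator emulates two-colony tracking, wind-at-departure and gridded
    fishing-effort data so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
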