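Package: occtrend
Title: Occupancy Trends from Opportunistic Biological Records Across
    Cropland Cover Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds visit-level detection histories from presence-only
    invertebrate records (target-group inferred non-detections, list-length
    effort categories), stratifies 1 km sites into high-, low- and
    no-cropland regions from land-cover composition, fits a hierarchical
    Bayesian occupancy-detection model with region-specific year effects
    under a random-walk prior, and derives multi-species geometric-mean
    occupancy indicators, annual growth rates and between-region effect
    sizes with full posterior uncertainty propagation. Includes a synthetic
    data generator that emulates opportunistic recording with known ground
    truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
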