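Package: resurveytrends
Title: Habitat-Specific Plant Diversity Trends from Vegetation-Plot Resurvey Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate local plant-diversity trends from repeated
    vegetation-plot surveys. Builds per-observation community indices
    (taxonomic, functional, phylogenetic, and species-group metrics with
    layer-overlap cover combination and coverage gates), fits per-series
    log-linear trends expressed as annual percentage change, pools them
    with observation-count or habitat-balanced weights, partitions trend
    variance across habitat types and habitat-change trajectories by
    dominance analysis, and estimates decadal gamma-diversity trends with
    sample-matched decade pairing. Includes a synthetic community
    generator with known ground-truth trends so the whole pipeline can be
    validated without access-restricted survey data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
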