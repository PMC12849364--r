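Package: pmedAccess
Title: Population-Weighted Travel-Time Optimization of Hospital Service
    Allocation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Countrywide facility-location analysis for hospital service
    planning. Builds population-weighted travel-time matrices between
    hexagonal-grid demand centroids and candidate hospital sites, selects p
    sites by an exact p-median mixed-integer program (with liberal and
    prioritized policy scenarios and per-pair or Big-M linking) or by a
    k-means allocation heuristic, and reports accessibility statistics:
    weighted and unweighted mean, median and interquartile range of travel
    time, the population share beyond a travel-time threshold, urban/rural
    stratification, distribution comparisons and hospital-quantity sweeps.
    Includes a synthetic-country generator (regionalized densities,
    urbanization classes, hexagonal demand grid, biased site placement) so
    the full pipeline runs without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
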