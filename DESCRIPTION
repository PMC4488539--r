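Package: sealforage
Title: Foraging Associations of a Benthic Marine Predator with Sea-Floor
    Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how anthropogenic sea-floor
    structures (pipelines, cable routes, wells, shipwrecks) influence the
    foraging behaviour of a central-place benthic marine predator tracked
    with GPS and time-depth recorders.  Provides dive detection and
    benthic/pelagic classification from depth traces, GPS track filtering
    and regularisation, first-passage diving analysis to locate intensive
    foraging, a presence-background maximum-entropy habitat model over a
    gridded covariate stack, buffer-based structure occupancy, and the
    downstream statistics (Kruskal-Wallis comparisons, AICc multimodel
    inference with model averaging).  A synthetic-data generator produces
    seascapes, structures, trips and depth traces with known ground truth
    so every stage is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
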