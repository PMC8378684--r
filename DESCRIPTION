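Package: winterdisp
Title: Winter Dispersal Geolocation, Fisheries Overlap and Trophic Niche
    Analysis for Magellanic Penguins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the non-breeding (winter) dispersal of
    Magellanic penguins tracked with light-level geolocators on the
    Patagonian Shelf. Implements probabilistic light-level geolocation
    (twilight inversion, particle clouds weighted by travelling speed,
    sea-surface-temperature match and land avoidance, geographic-median
    paths), per-individual track metrics with unequal-variance sex
    comparisons, gridded penguin-density by fishing-effort overlap and
    interaction scoring, stable-isotope niche metrics (standard ellipse
    areas and their Bayesian analogue, ellipse overlap) and Bayesian
    one- and two-baseline trophic-position estimation with trophic
    discrimination factors and Suess correction. A synthetic-data module
    generates ground-truthed tracks, tag records, fishing-effort fields
    and blood-isotope values for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    nlme,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
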