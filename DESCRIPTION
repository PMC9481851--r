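Package: allergiscape
Title: Community-Level Allergenicity of Urban Grasslands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based allergen annotation of vegetation-survey species
    lists and community-level allergenicity analysis along urbanisation and
    plant-invasion gradients. Species are scored with a multiplicative
    potential allergenic value (PAV, 0-36) from allergenicity, pollination
    syndrome and flowering duration; plot-level metrics (allergenic
    richness, proportion, cover, mean and cover-weighted mean PAV, allergen
    molecule and protein-family richness, monthly flowering profiles) are
    computed overall and by introduction status; gradients are tested with
    generalised linear models under AICc selection, distance-based
    redundancy analysis on Jaccard dissimilarities, Moran's I residual
    diagnostics, rarefaction of allergen protein families and bootstrap
    group comparisons. A seeded synthetic-data generator reproduces the
    statistical structure of dry-grassland surveys with known ground truth
    for end-to-end calibration and recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    jsonlite
Suggests:
    ape,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
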