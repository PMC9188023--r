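Package: debtraits
Title: Dynamic Energy Budget Life-History Traits and Comparative Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives eco-physiological life-history traits from standard
    Dynamic Energy Budget (DEB) parameter sets at a common reference
    temperature: initial reserve (egg energy) by a shooting method, ages and
    sizes at birth and puberty, von Bertalanffy growth, reproduction rate,
    weight-specific respiration, Weibull-Gompertz aging life span, supply
    stress and the precociality coefficient. Provides cross-species
    comparative statistics (trait survivor curves, taxon medians, log-log
    scaling fits), a symmetric bounded-loss trait distance with classical
    multidimensional scaling, and a seeded synthetic species generator based
    on DEB body-size covariation rules for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
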