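Package: mfsoil
Title: Multifunctional Soil Classification and Molecular Indicator Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies forest soils into multifunctional classes from
    standardized biogeochemical profiles (UPGMA clustering delineated by
    SIMPROF similarity-profile permutation tests), ranks classes by their
    Euclidean deviation from an unlogged reference condition, relates
    bacterial 16S rRNA gene community profiles to the environment through
    Hellinger-transformed redundancy analysis with double-stopping forward
    selection, and identifies rare-biosphere indicator OTUs for each class
    with permutation-validated IndVal statistics. Includes first-order
    trace-gas (H2, CO) uptake and linear CO2 production flux estimation
    from microcosm headspace time series, alpha/beta diversity summaries,
    and a synthetic-data generator that emulates a blocked silvicultural
    study design with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
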