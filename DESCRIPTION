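Package: seepscape
Title: Porewater Reaction-Transport Modeling and Microbial Community
    Analysis for Seep Sediment Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for habitat transects across hydrocarbon-seep
    sediments: a 1-D steady-state porewater reaction-transport model for
    sulfate and methane (forward solution of concentrations from volumetric
    rates, and inverse least-squares estimation of layer rates from measured
    concentration profiles), diffusive flux and depth-integrated rate
    calculations with flux/rate consistency checks, stable carbon isotope
    (delta-13C) utilities and upcore trend classification, furthest-neighbour
    OTU clustering with bias-corrected Chao1 richness estimation, joint
    geochemistry/community activity summaries, and a seeded synthetic-data
    generator that emulates the statistical structure of seep sediment cores
    and clone libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
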