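Package: nanodoe
Title: Design-of-Experiments Optimization and Release Kinetics for
    Nanoparticle Formulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the design-of-experiments
    workflow used to optimize ionic-gelation nanoparticle formulations:
    Plackett-Burman screening designs with main-effects ANOVA,
    Box-Behnken response-surface modelling on a composite desirability
    score (the geometric mean of min-max normalized responses),
    constrained optimization of the fitted quadratic surface, in-vitro
    drug-release kinetic model fitting (zero-order, first-order plateau,
    Higuchi, Ritger-Peppas), and closed-form assay metrics
    (encapsulation efficiency, drug loading, radical scavenging, cell
    viability). Seeded synthetic-data generators make every pipeline
    stage testable end-to-end, and an example Box-Behnken study of
    chitosan/TPP nanoparticles is packaged as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
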