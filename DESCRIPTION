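Package: hiveforage
Title: Optimal Allocation of Bee Foragers Between Simple and Complex Flowers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time optimization model of how a eusocial bee colony
    should split its foragers between 'simple' flowers (low, immediately
    accessible reward) and 'complex' flowers (high reward that each bee can
    only reach after a logistic learning period), subject to the colony
    keeping a non-negative nectar balance at every time step. Provides
    greedy, linear-programming and exhaustive-enumeration solvers for the
    forager switch schedule, seeded parameter sweeps over colony longevity,
    forager fraction, colony size, learning rate and forager survival, and a
    descriptive-analytics layer for bee-flower interaction tables (visit
    counts by flower symmetry and corolla depth, species-level visit
    proportions by sociality, a logistic-regression stand-in for
    phylogenetic mixed models) together with a synthetic interaction-table
    generator with a Brownian-motion species random effect on a simulated
    phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
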