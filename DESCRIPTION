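Package: woodimbibe
Title: Washburn Modelling of Liquid Imbibition in Wood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling spontaneous liquid imbibition in wood with the
    Lucas-Washburn approach extended to porous media. Provides closed-form and
    numerical solutions of the one-dimensional porous-medium Washburn equation
    with gravity and a stop-at-sample-length rule, a dual-scale two-dimensional
    network model coupling fast capillary rise in a latewood column to slow
    lateral Darcy invasion of earlywood (Kirchhoff flux conservation with a
    linear pressure solve per step), reduction of gravimetric microbalance
    recordings to equivalent-height kinetics (buoyancy correction, square-root-
    of-time slopes, permeability fitting), and a seeded synthetic-data generator
    emulating microbalance imbibition recordings for end-to-end parameter-recovery
    experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
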