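Package: neutrondose
Title: Analytical Modeling of Leakage Neutron Equivalent Dose in
    Passively Scattered Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates and trains an analytical model of the leakage-neutron
    equivalent dose per therapeutic absorbed dose (H/D) around passively
    scattered proton therapy beamlines. The model apportions H/D among four
    neutron energy regimes (intranuclear cascade, evaporation, epithermal,
    thermal), is continuous in proton beam energy from 100 to 250 MeV via a
    power-law isocenter calibration, and has a single-energy in-air variant
    for ocular beamlines. Includes constrained fitting of model parameters by
    minimizing local relative differences, a synthetic-data generator that
    reproduces published detector layouts, validation error reports, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
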