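Package: hsploc
Title: Hansen Solubility Parameters from Solvent Absorbance Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the three Hansen solubility parameters (dispersion,
    dipolar and hydrogen bonding) of materials that resist bottom-up
    prediction, such as amorphous porous organic polymers, from UV/vis
    absorbances of their suspensions in a small panel of solvents with known
    parameters. The estimate is the absorbance-weighted centroid in Hansen
    space, obtained by fixed-step gradient descent on the total weighted
    Hansen distance from a closed-form squared-cost initialization. Includes
    a CAS-indexed solvent parameter database, solvent ranking and
    distance-decomposition reports, grid-search and multistart validation
    oracles, a seeded synthetic-panel generator for parameter-recovery
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
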