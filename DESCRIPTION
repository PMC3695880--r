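Package: uprsim
Title: Kinetic Modelling and Bifurcation Analysis of the Unfolded Protein Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and analyses an integrated ordinary-differential-equation
    model of the mammalian unfolded protein response (UPR): the IRE1alpha,
    PERK and ATF6 signalling branches coupled to a bistable BAX/BAK/BH3
    apoptosis switch. Provides total quasi-steady-state (extended
    Michaelis-Menten) and competitive multi-regulator rate laws, modular
    network assembly with knockout and variant switches, stiff ODE and
    delay-differential integration under piecewise-constant stress protocols,
    steady-state continuation with Hopf and fold detection, limit-cycle
    envelopes and hysteresis analysis, ABC-SMC mapping of the oscillatory
    parameter region, reproducible stress and preconditioning scenarios, and
    SBML Level 2 Version 4 export/import.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
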