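Package: turbsim
Title: Heat and Water-Vapor Exchange in the Nasal Turbinates of Seals
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-1D, time-dependent simulation of coupled heat and water-vapor
    transport in the maxilloturbinate region of a seal's nasal cavity. Five coupled
    subsystems (air, mucus lining, interstitial tissue, artery, vein) exchange
    sensible heat and water over a breathing cycle driven by a sinusoidal tidal
    flow; the air-mucus interface uses a coupled force-flux law from
    nonequilibrium thermodynamics with a positive semi-definite resistance matrix.
    The solver integrates the area-averaged balance equations by the method of
    lines (fourth-order upwind-biased differences, stiff backward-differentiation
    integration) to a cyclic steady state, and post-processing computes entropy
    production, lost work, heat and water loss and recovery, and the expired-air
    temperature regression used to compare Arctic and subtropical seal geometries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
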