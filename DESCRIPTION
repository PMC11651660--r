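Package: covalentCA
Title: Characterization of Covalent Carbonic Anhydrase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for pre-vinylsulfone covalent inhibitors of
    carbonic anhydrase isozymes. Provides exact-mass bookkeeping for
    covalent adducts (molecular formula parsing, monoisotopic and average
    masses, ion m/z, leaving-group mass-shift prediction and matching
    against deconvoluted intact-protein mass peaks), two-state thermal
    unfolding melt-curve fitting and ThermoFluor dosing-curve analysis for
    apparent dissociation constants, a depletion-aware competitive binding
    equilibrium solver for fluorescent-probe displacement on live cells,
    an ODE simulator of the two-step covalent inhibition kinetic scheme
    (time-dependent IC50 collapse, dialysis washout), and seeded synthetic
    data generators emulating the corresponding assay plate layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
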