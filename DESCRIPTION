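Package: primext
Title: Binding and Kinetic Modelling of Enzyme-Free Primer Extension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative modelling of enzyme-free, template-directed
    primer extension. Extracts nucleotide-template dissociation constants
    from NMR chemical-shift titrations (single-site isotherm, exact 1:1
    quadratic or ligand-excess forms) and from competitive-inhibition
    kinetics (pseudo-first-order time courses, reciprocal-rate
    linearization and global fits), computes extension-site occupancy
    isotherms, and predicts time-dependent extension yields under
    concurrent monomer hydrolysis via a closed-form expression and an
    ODE generalization. Ships transcribed dissociation-constant tables,
    synthetic-data generators with the statistical structure the assays
    assume, CSV/JSON input-output and a thin command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
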