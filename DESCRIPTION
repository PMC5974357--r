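Package: orgflux
Title: Steady-State Flux of Spatially Organized Two-Enzyme Pathways in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially resolved steady-state kinetic model of a sequential
    two-enzyme Michaelis-Menten pathway in a spherical bacterial cell under
    three organization strategies: encapsulation in a microcompartment-like
    organelle, co-localization on a scaffold, and free cytosolic enzymes.
    Provides a closed-form-plus-root-finding solver for the organized cases
    (well-mixed compartment, Laplace cytosol shell), a conservative
    finite-volume boundary-value solver for the unorganized case and for
    full-resolution validation, per-cell pathway flux and intermediate
    leakage metrics, one-dimensional parameter sweeps and two-dimensional
    optimal-strategy maps over kinetic, transport and culture parameters,
    literature-observation-to-flux calibration helpers, and a command-line
    interface.  Ships parameter presets for the Salmonella Pdu
    microcompartment pathway and for heterologous mevalonate biosynthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
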