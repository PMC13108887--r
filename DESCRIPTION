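Package: vesiclepf
Title: Phase-Field Simulation of Vesicle Membranes with Area-Difference
    Elasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional diffuse-interface (phase-field) modelling of
    lipid-bilayer vesicles. Implements a relaxed Willmore/Helfrich bending
    energy together with an area-difference-elasticity (ADE) term and soft
    penalty constraints on interior volume and membrane area, and relaxes
    the total energy by an Allen-Cahn type gradient flow. Spatial operators
    are Fourier-spectral on a periodic cubic grid; time integrators include
    forward Euler, a linearly implicit (semi-implicit) spectral scheme and a
    fully implicit symmetrized scheme that satisfies a discrete energy
    dissipation law. Ships analytic tanh initial shapes, presets for a range
    of vesicle morphologies (discocyte, torus, budding/fission series,
    multi-armed, nested, pear), shape diagnostics (reduced volume, reduced
    area difference, connected-component and arm counts, reflection
    asymmetry), VTK snapshot export and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
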