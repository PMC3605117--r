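Package: uterowave
Title: Multiscale Forward Electromagnetic Modelling of Uterine Contractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling of the electromagnetic fields generated by
    myometrial contractions during pregnancy. Couples a modified
    FitzHugh-Nagumo ionic model with a plateau-type action potential to an
    anisotropic monodomain reaction-diffusion solver on spherical uterine
    geometries, solves the quasi-static volume-conductor problem for the
    abdominal surface potential (EMG), and computes the abdominal magnetic
    field (MMG) by Biot-Savart quadrature over the total current density.
    Includes Archie's-law estimation of myometrial conductivities, design of
    cylindrically symmetric conductivity tensor fields from fiber
    orientations, structured simplicial mesh generation for multi-compartment
    spherical volume conductors, waveform and contracting-volume metrics, and
    a config-driven simulation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
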