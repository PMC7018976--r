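Package: nanobead
Title: Bead Morphology of Heterogeneous Membrane Nanotubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum-mechanics model of membrane nanotubes with
    heterogeneous composition. Implements an augmented Helfrich energy in
    which a locally phase-separated protein density induces spontaneous
    curvature and altered bending rigidity, reduces the resulting shape and
    tension equations to a first-order ODE system on an axisymmetric surface,
    and solves the six-point boundary-value problem by Newton collocation
    with parameter continuation. Provides closed-form limit results for the
    curvature and radius of protein-induced beads, bead detection and
    shape classification (ellipsoidal, cylindrical, unduloid), length-scale
    phase diagrams, and two-domain merge studies with snap-through
    (hysteresis) detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
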