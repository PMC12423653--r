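Package: swimmodes
Title: Modal Analysis and Optimization of Active Swimming Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the linearized elastohydrodynamics of internally
    forced slender filaments in Stokes flow. Constructs the complex
    Green's function of the time-harmonic hyperdiffusion operator,
    assembles the real symmetric swimming-speed kernel linking an
    internal moment-forcing profile directly to the reduced swimming
    speed, eigendecomposes the kernel into orthonormal forcing modes,
    solves the analytic four-mode eigensystem for monophasic (in-phase)
    forcing, and optimizes piecewise-constant and discrete-actuator
    swimmer designs under forcing-magnitude constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
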