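Package: ergomap
Title: Ergodic Iterated Maps with Prescribed Invariant Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs deterministic iterated maps whose orbits are ergodic
    for a prescribed target probability distribution, in one or several
    dimensions, by conjugating a Lebesgue-measure-preserving ("uniform") map
    on the unit hypercube with the forward and inverse Rosenblatt
    transformations of the target.  Provides analytic one-dimensional density
    families and piecewise-constant grid densities (including densities read
    from greyscale images), a catalog of uniform maps with exact Lyapunov
    exponents, orbit generation with a finite-precision guard, and dynamical
    diagnostics: empirical and theoretical Lyapunov exponents, transfer
    operator invariance residuals, ergodic averages, and orbit-versus-target
    distribution distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
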