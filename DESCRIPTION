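Package: lgmf
Title: Optimal Mechanical Forces Tuning the Energy Gap Between Two
    Electronic States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds, for each prescribed external-force magnitude, the
    applied mechanical force producing the largest increase or decrease of
    the energy gap between two electronic potential energy surfaces.
    Implements the closed-form solution on quadratic (second-order)
    surfaces via a Lagrange-multiplier scan and secular equation, and the
    iterative LGMF (Largest energy Gap variation with Minimal mechanical
    Force) algorithm on general surfaces: a predictor step at fixed
    force-magnitude increment, a corrector projection enforcing the
    parallelism of the gap gradient and the force-magnitude gradient,
    exact verification, and quasi-Newton (BFGS) Hessian updating. Includes
    analytic model surfaces, a seeded fixture generator, a dense
    constrained-search oracle, translation/rotation projection,
    force-pair decomposition, unit conversion, and XYZ/JSON/CSV
    input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
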