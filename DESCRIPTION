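Package: ocupk
Title: Physiology-Based Ocular Pharmacokinetics of Drug-Eluting Contact Lenses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of drug delivery from a soft contact lens
    to the anterior and posterior segments of the eye. Couples a
    one-dimensional diffusion equation across the lens thickness to
    compartmental mass balances for the tears, sclera-choroid, retina,
    vitreous humor and aqueous humor, with the corneal epithelium evaluated
    as an equilibrium compartment. Includes an alternative release-driven
    source mode fed by an exponential fit of in vitro cumulative-release
    data, aqueous bioavailability computation from in vivo concentration
    series, exposure metrics (AUC, Cmax), mass-balance auditing,
    one-at-a-time local sensitivity analysis and randomized-parameter
    uncertainty propagation, plus seeded synthetic-data generators for
    every fitting operation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
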