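Package: twopatch
Title: Dispersal and Asymptotic Total Population Size in Two-Patch Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how symmetric dispersal between two
    heterogeneous habitat patches affects the asymptotic total population
    size. Implements the discrete-time Beverton-Holt two-patch map and its
    continuous-time logistic analogue, numerical computation of the unique
    positive equilibrium, the dispersal-response function H, closed-form
    expressions for its zeros, maxima and derivatives, and exact
    parameter-condition classifiers for the four qualitative response
    scenarios (monotonically beneficial, unimodally beneficial, beneficial
    turning detrimental, monotonically detrimental). Includes plotting of
    response curves, the graphical equilibrium construction for the
    discrete map, a seeded generator of parameter sets inside each
    scenario region, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
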