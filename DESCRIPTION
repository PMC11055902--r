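Package: fbqpop
Title: Fuzzy Bobwhite Quail Population Dynamics Under g-Division
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and stability analysis of a third-order rational
    difference-equation model of bobwhite quail population dynamics,
    x[n+1] = A + B*x[n] + x[n]/(x[n-1]*x[n-2]), in which the growth
    parameters A, B and the three initial population sizes are positive
    fuzzy numbers represented by alpha-cut endpoint families. Fuzzy
    arithmetic uses the generalized (g-) division of fuzzy numbers, with
    the Zadeh extension-principle division available for comparison.
    Provides alpha-cut interval arithmetic for positive fuzzy numbers,
    per-level endpoint recursions for both g-division cases with automatic
    per-step case classification, closed-form crisp and fuzzy equilibria,
    boundedness and persistence envelopes, linearized-stability reports,
    checkers for the model's sufficient stability conditions, scenario
    generators (including a reference parabolic-fuzzy-number scenario and
    regime-constrained random scenarios), equilibrium table reproduction,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
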