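Package: switchscan
Title: Detecting Bistability and Output Switchability in Polynomial
    Reaction-Network Models with Groebner Bases
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact-arithmetic analysis of fixed-point bistability and output
    switchability in biochemical reaction networks and other polynomial or
    rational ODE models.  Builds mass-action steady-state systems with exact
    rational coefficients, computes reduced lexicographic Groebner bases with
    an internal Buchberger engine (arbitrary-precision rational arithmetic),
    solves the resulting triangular systems by Sturm-sequence real-root
    isolation and back-substitution, classifies steady states by Jacobian
    eigenvalues, applies cubic-discriminant conditions for switchable outputs,
    brackets saddle-node boundaries by parameter scans with bisection, and
    synthesizes mass-action networks realizing a prescribed univariate cubic.
    Ships curated signalling-pathway models (AKT, MAPK dual phosphorylation,
    RAS) and classic small bistable networks as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'rational.R'
    'AllClasses.R'
    'poly.R'
    'parse.R'
    'model.R'
    'groebner.R'
    'steady_states.R'
    'stability.R'
    'switchability.R'
    'bifurcation.R'
    'dynamics.R'
    'design.R'
    'fixtures.R'
    'report.R'
    'cli.R'
    'zzz.R'
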