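# Central S4 containers.

#' Multivariate polynomial with exact rational coefficients
#'
#' The universal currency of the pipeline: a sparse multivariate polynomial
#' over the rationals.  Terms are stored as an exponent matrix (one row per
#' term, one column per variable) plus coefficient strings in canonical
#' rational form, sorted in descending lexicographic order with the first
#' variable ranked highest.
#'
#' @slot vars character vector of variable names (column order = lex ranking
#'   used for internal storage; reorderings are handled by the basis
#'   functions, not by the object)
#' @slot exps integer matrix of exponents, terms x variables
#' @slot coefs character vector of canonical rational coefficients
#' @seealso [qpoly()], [parsePolynomial()]
#' @export
setClass("QPolynomial", representation(
  vars = "character",
  exps = "matrix",
  coefs = "character"
), validity = function(object) {
  if (nrow(object@exps) != length(object@coefs))
    return("number of exponent rows must equal number of coefficients")
  if (ncol(object@exps) != length(object@vars))
    return("number of exponent columns must equal number of variables")
  if (length(object@vars) && anyDuplicated(object@vars))
    return("duplicated variable names")
  if (length(object@exps) && any(object@exps < 0))
    return("negative exponents are not allowed")
  TRUE
})

#' Conservation constraint
#'
#' A linear relation `sum(coefficients * x) == total` among species, used to
#' close differential-algebraic models (conserved moieties such as total
#' kinase).  The eliminated species is reconstructed and checked for
#' nonnegativity whenever steady states are reported.
#'
#' @slot coefficients named character vector of exact rational coefficients
#' @slot total exact rational string, the conserved total
#' @slot victim name of the variable to eliminate (`NA` = choose the
#'   largest-index constraint variable present in the system)
#' @export
setClass("ConservationConstraint", representation(
  coefficients = "character",
  total = "character",
  victim = "character"
), validity = function(object) {
  if (is.null(names(object@coefficients)) || any(!nzchar(names(object@coefficients))))
    return("constraint coefficients must be named by variable")
  if (length(object@coefficients) < 2)
    return("a conservation constraint must involve at least two variables")
  if (cpp_rat_cmp(object@total, "0") < 0)
    return("conserved total must be nonnegative")
  TRUE
})

#' Mass-action reaction network
#'
#' @slot species character vector of dynamic species
#' @slot fixed character vector of species with clamped concentration
#'   (inert products and lumped reactants); they may appear in reactions but
#'   contribute no ODE, and their concentrations are folded into the rate
#'   constants
#' @slot reactions list of reaction records as created by [reaction()]
#' @slot parameters named character vector of exact rational rate constants
#' @export
setClass("ReactionNetwork", representation(
  species = "character",
  fixed = "character",
  reactions = "list",
  parameters = "character"
), validity = function(object) {
  for (r in object@reactions) {
    bad <- setdiff(c(names(r$reactants), names(r$products)),
                   c(object@species, object@fixed))
    if (length(bad))
      return(paste0("unknown species in reaction: ", paste(bad, collapse = ", ")))
    if (length(r$reactants) && any(unlist(r$reactants) <= 0))
      return("reactant stoichiometries must be positive integers")
  }
  TRUE
})

#' Polynomial / rational ODE system
#'
#' `dx_i/dt = f_i(x) / d_i(x)` with exact rational coefficients.  Mass-action
#' systems have constant denominator 1; Michaelis-Menten style rate laws
#' yield nontrivial denominators after clearing.  Conserved species
#' eliminated through constraints are kept in `eliminated` as linear
#' expressions of the remaining state and reconstructed on reporting.
#'
#' @slot variables ordered character vector of state variables
#' @slot numerators list of [QPolynomial] (f_i)
#' @slot denominators list of [QPolynomial] (d_i)
#' @slot parameters named character vector of exact rational parameter values
#' @slot constraintList list of [ConservationConstraint]
#' @slot eliminated named list: eliminated variable -> [QPolynomial] linear
#'   expression in the remaining variables
#' @slot definition list holding the symbolic source (expressions or
#'   reactions plus the raw parameter map) so the system can be rebuilt with
#'   modified parameters for bifurcation scans
#' @slot metadata list (fixture name, declared outputs, preferred lex order,
#'   scan window, ...)
#' @export
setClass("RationalODESystem", representation(
  variables = "character",
  numerators = "list",
  denominators = "list",
  parameters = "character",
  constraintList = "list",
  eliminated = "list",
  definition = "list",
  metadata = "list"
), validity = function(object) {
  n <- length(object@variables)
  if (length(object@numerators) != n || length(object@denominators) != n)
    return("one numerator and one denominator polynomial per variable required")
  for (p in c(object@numerators, object@denominators)) {
    if (!is(p, "QPolynomial")) return("rhs entries must be QPolynomial")
    if (!identical(p@vars, object@variables))
      return("rhs polynomials must share the system's variable order")
  }
  for (d in object@denominators) {
    if (nrow(d@exps) == 0) return("zero denominator polynomial")
  }
  if (anyDuplicated(object@variables)) return("duplicated variable names")
  TRUE
})

#' Reduced lexicographic Groebner basis
#'
#' @slot polys list of monic, inter-reduced [QPolynomial] generating the same
#'   ideal as the input, sorted by increasing leading monomial (the univariate
#'   element, when present, comes first)
#' @slot ranking character vector: lex ranking, highest first; the univariate
#'   basis polynomial (when the ideal is zero-dimensional) lives in the last
#'   (lowest-ranked) variable
#' @slot backend "internal", "sympy" or "both"
#' @slot pairsProcessed number of S-pairs the internal engine consumed
#' @export
setClass("GroebnerBasisResult", representation(
  polys = "list",
  ranking = "character",
  backend = "character",
  pairsProcessed = "numeric"
))

#' Full analysis report
#'
#' Output of [analyzeModel()]: the Groebner bases used, all steady states
#' with admissibility and stability annotations, the bistability verdict and
#' one switchability report per requested output.
#'
#' @slot model model identifier
#' @slot system the analyzed [RationalODESystem]
#' @slot basis primary [GroebnerBasisResult]
#' @slot states data.frame of steady states (one column per variable,
#'   plus admissible/reason/component/label/maxRe columns)
#' @slot verdict list: status, admissible count, label pattern
#' @slot switchability named list of per-output reports
#' @slot scan optional scan result list
#' @slot meta tool metadata (version, timings, tolerances)
#' @export
setClass("AnalysisReport", representation(
  model = "character",
  system = "RationalODESystem",
  basis = "GroebnerBasisResult",
  states = "data.frame",
  verdict = "list",
  switchability = "list",
  scan = "list",
  meta = "list"
))
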