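#' @useDynLib switchscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is show
#' @importFrom stats setNames
#' @importFrom utils head tail modifyList
NULL

#' Variables of an algebraic object
#'
#' @param x a [QPolynomial], [RationalODESystem] or [GroebnerBasisResult]
#' @return character vector of variable names
#' @export
setGeneric("variables", function(x) standardGeneric("variables"))

#' Parameter map of a model object
#'
#' @param x a [ReactionNetwork] or [RationalODESystem]
#' @return named character vector of exact rational parameter values
#' @export
setGeneric("parameters", function(x) standardGeneric("parameters"))

#' Dynamic species of a reaction network
#'
#' @param x a [ReactionNetwork]
#' @return character vector of species names
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Reactions of a reaction network
#'
#' @param x a [ReactionNetwork]
#' @return list of reaction records
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' Right-hand-side numerator polynomials of an ODE system
#'
#' @param x a [RationalODESystem]
#' @return list of [QPolynomial], one per variable
#' @export
setGeneric("rhsNumerators", function(x) standardGeneric("rhsNumerators"))

#' Right-hand-side denominator polynomials of an ODE system
#'
#' @param x a [RationalODESystem]
#' @return list of [QPolynomial], one per variable (constant 1 for mass action)
#' @export
setGeneric("rhsDenominators", function(x) standardGeneric("rhsDenominators"))

#' Conservation constraints attached to a system
#'
#' @param x a [RationalODESystem]
#' @return list of [ConservationConstraint]
#' @export
setGeneric("constraints", function(x) standardGeneric("constraints"))

#' Basis polynomials of a Groebner basis result
#'
#' @param x a [GroebnerBasisResult]
#' @return list of monic [QPolynomial] sorted by increasing leading monomial
#' @export
setGeneric("basisPolys", function(x) standardGeneric("basisPolys"))

#' Lexicographic variable ranking used for a basis
#'
#' @param x a [GroebnerBasisResult]
#' @return character vector, highest-ranked variable first
#' @export
setGeneric("lexRanking", function(x) standardGeneric("lexRanking"))
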