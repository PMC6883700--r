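# Reduced lexicographic Groebner bases: internal Buchberger engine with an
# optional external CAS (sympy) cross-check backend.

.as_poly_list <- function(x) {
  if (is(x, "RationalODESystem")) return(steadyStatePolys(x))
  if (is(x, "QPolynomial")) return(list(x))
  stopifnot(is.list(x))
  x
}

.switchscan_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "switchscanError")))
}

#' Reduced lexicographic Groebner basis
#'
#' Computes the unique reduced, monic, inter-reduced Groebner basis of the
#' ideal generated by `polys` under the lexicographic order given by
#' `ranking` (highest-priority variable first).  The default backend is the
#' internal Buchberger engine with exact big-rational arithmetic (normal
#' pair-selection strategy, product and chain criteria, deterministic
#' tie-breaks); `backend = "sympy"` delegates to the external CAS through the
#' command-line `python`, and `backend = "both"` runs both and errors on any
#' disagreement (the reduced basis is unique, so agreement is exact).
#'
#' @param polys list of [QPolynomial] (or a [RationalODESystem], whose
#'   steady-state numerators are used)
#' @param ranking character permutation of the variables, highest first; the
#'   univariate basis polynomial of a zero-dimensional ideal lives in the
#'   *last* (lowest-ranked) variable
#' @param backend `"internal"`, `"sympy"` or `"both"`
#' @param pairCap resource guard: maximum number of S-pairs the internal
#'   engine may process before failing loudly (lex bases can blow up)
#' @return a [GroebnerBasisResult]
#' @examples
#' x <- qpVar(c("x", "y"), "x"); y <- qpVar(c("x", "y"), "y")
#' f1 <- 16 * y - x^2 - x * y - "3/2" * x
#' f2 <- x^2 - 8 * y
#' gb <- groebnerBasis(list(f1, f2), ranking = c("y", "x"))
#' basisPolys(gb)   # univariate in x: x^3 - 8 x^2 + 12 x (monic)
#' @export
groebnerBasis <- function(polys, ranking = NULL,
                          backend = c("internal", "sympy", "both"),
                          pairCap = 20000) {
  backend <- match.arg(backend)
  polys <- .as_poly_list(polys)
  if (!length(polys)) stop("empty polynomial system")
  vars <- variables(polys[[1]])
  if (is.null(ranking)) ranking <- vars
  if (!setequal(ranking, vars) || length(ranking) != length(vars))
    stop("ranking must be a permutation of the system variables")
  nonzero <- Filter(Negate(qpIsZero), polys)
  if (!length(nonzero)) stop("all input polynomials are zero")
  reord <- lapply(nonzero, .reorder_poly, ranking = ranking)
  runInternal <- function() {
    G <- cpp_buchberger(lapply(reord, .qp_list), pairCap)
    list(polys = lapply(G, .qp_from_list, vars = ranking),
         pairs = attr(G, "pairsProcessed"))
  }
  runSympy <- function() list(polys = .sympy_groebner(reord, ranking), pairs = NA_real_)
  res <- switch(backend,
                internal = runInternal(),
                sympy = runSympy(),
                both = {
                  a <- runInternal()
                  b <- runSympy()
                  if (!.basis_identical(a$polys, b$polys))
                    stop("internal and sympy Groebner bases disagree")
                  a
                })
  # store basis polynomials in the caller's variable order; the ranking is
  # carried separately
  new("GroebnerBasisResult",
      polys = lapply(res$polys, .reorder_poly, ranking = vars),
      ranking = ranking,
      backend = backend, pairsProcessed = as.numeric(res$pairs))
}

.basis_identical <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  key <- function(p) paste(formatPoly(p), collapse = "")
  identical(sort(vapply(a, key, character(1))), sort(vapply(b, key, character(1))))
}

.sympy_available <- function() {
  nzchar(Sys.which("python")) &&
    isTRUE(tryCatch(system2("python", c("-c", "import sympy"),
                            stdout = FALSE, stderr = FALSE) == 0,
                    error = function(e) FALSE, warning = function(w) FALSE))
}

.sympy_groebner <- function(reordPolys, ranking) {
  script <- system.file("python", "groebner_oracle.py", package = "switchscan")
  if (!nzchar(script)) stop("sympy oracle script not found")
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  payload <- list(
    nvars = length(ranking),
    polys = lapply(reordPolys, function(p)
      list(exps = unclass(p@exps), coefs = p@coefs))
  )
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  status <- system2("python", c(script, infile, outfile), stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) stop("sympy oracle failed (exit ", status, ")")
  res <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)
  lapply(res, function(p) {
    exps <- do.call(rbind, lapply(p$exps, function(row) as.integer(unlist(row))))
    if (is.null(exps)) exps <- matrix(0L, 0, length(ranking))
    qpoly(ranking, exps, unlist(p$coefs))
  })
}

#' @export
setMethod("basisPolys", "GroebnerBasisResult", function(x) x@polys)

#' @export
setMethod("lexRanking", "GroebnerBasisResult", function(x) x@ranking)

#' @export
setMethod("variables", "GroebnerBasisResult", function(x) x@ranking)

setMethod("show", "GroebnerBasisResult", function(object) {
  cat("Reduced lex Groebner basis (", paste(object@ranking, collapse = " > "),
      "), ", length(object@polys), " polynomial(s):\n", sep = "")
  for (g in object@polys) cat("  ", formatPoly(g), "\n", sep = "")
})

#' Is the ideal zero-dimensional?
#'
#' Standard criterion on a Groebner basis: for every variable some basis
#' element's leading monomial is a pure power of that variable.
#'
#' @param gb a [GroebnerBasisResult]
#' @return logical
#' @export
isZeroDimensional <- function(gb) {
  lts <- lapply(gb@polys, function(p) leadingTerm(p, gb@ranking)$exps)
  all(vapply(gb@ranking, function(v) {
    any(vapply(lts, function(e) e[[v]] > 0 && sum(e) == e[[v]], logical(1)))
  }, logical(1)))
}

#' Extract the triangular chain from a reduced lex basis
#'
#' Identifies the univariate basis polynomial `g1` in the lowest-ranked
#' variable and orders the remaining polynomials by the highest-ranked
#' variable they introduce.  The basis may contain more than `n` polynomials;
#' all are retained for the consistency checks during back-substitution.
#'
#' @param gb a [GroebnerBasisResult]
#' @return list with components `univariate` (a [QPolynomial]), `chain`
#'   (all basis polynomials in solving order) and `ranking`
#' @section Errors: signals a condition of class `noUnivariateError` when no
#'   basis element is univariate in the lowest-ranked variable, and
#'   `notZeroDimensionalError` when the solution set is not finite.
#' @export
extractTriangular <- function(gb) {
  ranking <- gb@ranking
  uniVar <- ranking[length(ranking)]
  uni <- Filter(function(p) all(qpVarsUsed(p) %in% uniVar), gb@polys)
  if (!length(uni))
    .switchscan_error(paste0("the univariate basis polynomial in '", uniVar,
                             "' does not exist for this ordering"),
                      "noUnivariateError")
  if (!isZeroDimensional(gb))
    .switchscan_error("solution set is not finite (ideal is not zero-dimensional)",
                      "notZeroDimensionalError")
  # solving order: by the highest-ranked variable each polynomial involves,
  # starting from the univariate element
  level <- vapply(gb@polys, function(p) {
    used <- qpVarsUsed(p)
    min(match(used, ranking))
  }, numeric(1))
  ord <- order(-level, vapply(gb@polys, qpDegree, integer(1)))
  list(univariate = uni[[1]], chain = gb@polys[ord], ranking = ranking)
}

#' Univariate basis polynomial in a chosen variable
#'
#' Recomputes the basis with `var` ranked last if needed and returns the
#' univariate element, or `NULL` when it does not exist (e.g. when the
#' chosen output does not admit an elimination polynomial, as happens for
#' some orderings of factorized networks).
#'
#' @param polys list of [QPolynomial] / [RationalODESystem]
#' @param var variable the univariate polynomial should live in
#' @param ... passed to [groebnerBasis()]
#' @return a [QPolynomial] or `NULL`
#' @export
univariateIn <- function(polys, var, ...) {
  polys <- .as_poly_list(polys)
  vars <- variables(polys[[1]])
  if (!var %in% vars) stop("unknown variable: ", var)
  ranking <- c(setdiff(vars, var), var)
  gb <- groebnerBasis(polys, ranking, ...)
  tri <- tryCatch(extractTriangular(gb),
                  noUnivariateError = function(e) NULL,
                  notZeroDimensionalError = function(e) NULL)
  if (is.null(tri)) NULL else tri$univariate
}
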