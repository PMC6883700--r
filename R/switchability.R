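# Output switchability: the normalized-cubic conditions, the repeated-root
# rule, and the fallback comparison of output values at the stable states.
# The rules are shortcuts; the defining property (different output values at
# the two stable steady states) is always computed alongside.

#' Discriminant of the normalized cubic
#'
#' For `g1(x) = -x^3 + b x^2 - c x + d` the discriminant is
#' `D = -27 d^2 + 18 b c d - 4 c^3 - 4 b^3 d + b^2 c^2`; `D > 0` iff the
#' cubic has three distinct real roots.
#'
#' @param b,c,d coefficients, as rational strings (exact result) or numerics
#'   (double result)
#' @return rational string when all inputs are strings, double otherwise
#' @examples
#' cubicDiscriminant("8", "12", "0")   # 2304: three distinct roots 0, 2, 6
#' cubicDiscriminant("6", "11", "6")   # 4:    roots 1, 2, 3
#' @export
cubicDiscriminant <- function(b, c, d) {
  if (is.character(b) && is.character(c) && is.character(d)) {
    b <- cpp_rat_norm(b); c <- cpp_rat_norm(c); d <- cpp_rat_norm(d)
    M <- function(...) Reduce(function(x, y) cpp_rat_arith("mul", x, y), list(...))
    A <- function(x, y) cpp_rat_arith("add", x, y)
    terms <- list(M("-27", d, d), M("18", b, c, d), M("-4", c, c, c),
                  M("-4", b, b, b, d), M(b, b, c, c))
    Reduce(A, terms)
  } else {
    b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
    -27 * d^2 + 18 * b * c * d - 4 * c^3 - 4 * b^3 * d + b^2 * c^2
  }
}

#' Normalize a univariate cubic and test the switchability conditions
#'
#' The basis polynomial is scaled to leading coefficient -1, giving
#' `g1(x) = -x^3 + b x^2 - c x + d`.  The test passes iff `b > 0`, `c > 0`,
#' `d >= 0` and the discriminant `D > 0`: by Descartes' rule of signs
#' (no sign changes in `g1(-x)`) all roots are then nonnegative, and `D > 0`
#' makes the three real roots distinct.  All comparisons are exact.
#'
#' @param p a [QPolynomial] univariate of degree exactly 3 (other degrees
#'   signal a `notCubicError` condition and are routed to the direct
#'   output-value comparison by [outputSwitchable()])
#' @param var variable name (defaults to the single variable used)
#' @return list with exact strings `b`, `c`, `d`, `D`, logical `pass`, and
#'   `conditions` (named logicals for b>0, c>0, d>=0, D>0)
#' @examples
#' g1 <- qpFromUniCoefs("x", c("0", "-12", "8", "-1"))  # 8x^2 - x^3 - 12x
#' cubicSwitchTest(g1)
#' @export
cubicSwitchTest <- function(p, var = NULL) {
  used <- qpVarsUsed(p)
  if (length(used) > 1) stop("polynomial is not univariate")
  v <- if (!is.null(var)) var else if (length(used)) used else p@vars[1]
  co <- qpUniCoefs(p, v)
  if (length(co) != 4)
    .switchscan_error(paste0("univariate basis polynomial has degree ",
                             length(co) - 1L, ", not 3"), "notCubicError")
  lead <- co[4]
  s <- cpp_rat_arith("div", "-1", lead)   # scale so the leading coefficient is -1
  co <- vapply(co, function(x) cpp_rat_arith("mul", x, s), character(1),
               USE.NAMES = FALSE)
  b <- co[3]
  c <- cpp_rat_arith("mul", "-1", co[2])
  d <- co[1]
  D <- cubicDiscriminant(b, c, d)
  conditions <- c(`b>0` = cpp_rat_cmp(b, "0") > 0,
                  `c>0` = cpp_rat_cmp(c, "0") > 0,
                  `d>=0` = cpp_rat_cmp(d, "0") >= 0,
                  `D>0` = cpp_rat_cmp(D, "0") > 0)
  list(b = b, c = c, d = d, D = D,
       pass = all(conditions), conditions = conditions)
}

#' Monic cubic through three admissible output values
#'
#' When the exact univariate basis polynomial has degree above three (extra
#' roots killed by the admissibility filter, e.g. negative-concentration or
#' denominator-vanishing branches), the cubic relevant for switchability is
#' the one whose roots are the three admissible output values; its
#' normalized coefficients (b, c, d) are reported alongside the fallback
#' verdict.
#'
#' @param roots numeric vector of length 3
#' @return list with numeric `b`, `c`, `d` of `-x^3 + b x^2 - c x + d`
#' @export
admissibleCubic <- function(roots) {
  stopifnot(length(roots) == 3)
  list(b = sum(roots),
       c = roots[1] * roots[2] + roots[1] * roots[3] + roots[2] * roots[3],
       d = roots[1] * roots[2] * roots[3])
}

#' Repeated-root rule for output switchability
#'
#' When the univariate polynomial in the output has fewer roots than the
#' system has steady states, some root is repeated across states.  The
#' bistable system is then switchable in that output only if the repetition
#' involves the unstable state: a value shared by both *stable* states
#' cannot switch.
#'
#' @param stableVals output values at the two stable states
#' @param unstableVal output value at the unstable state
#' @param tol distinctness tolerance
#' @return list with `switchable` (logical) and `why`
#' @examples
#' repeatedRootRule(c(9, 9), 10)    # not switchable: 9 repeated on the stable pair
#' repeatedRootRule(c(1, 3), 3)     # switchable: repetition involves the unstable state
#' @export
repeatedRootRule <- function(stableVals, unstableVal, tol = 1e-8) {
  stopifnot(length(stableVals) == 2)
  scale <- 1 + max(abs(c(stableVals, unstableVal)))
  stableRepeat <- abs(stableVals[1] - stableVals[2]) <= tol * scale
  if (stableRepeat) {
    list(switchable = FALSE,
         why = "repeated output value sits on both stable states")
  } else {
    list(switchable = TRUE,
         why = "stable-state output values differ; any repetition involves the unstable state")
  }
}

#' Switchability verdict for one output variable
#'
#' Applies the analysis-procedure routing: (a) if the univariate basis
#' polynomial in the output exists and is cubic, the normalized-cubic
#' conditions decide (confirmed against the state table); (b) if it exists
#' with repeated or too few roots, the repeated-root rule decides; (c) if it
#' does not exist (or has degree above three), the output values at the two
#' stable states are compared directly.  The direct comparison is also run
#' in every case as ground truth; switchability is `"undefined"` when the
#' system is not bistable.
#'
#' @param system a [RationalODESystem]
#' @param records classified state table ([stabilityRecords()])
#' @param verdict result of [bistabilityVerdict()]
#' @param output output variable name
#' @param solve the [solveSteadyStates()] result (supplies the component
#'   polynomials for univariate recomputation); may be `NULL`
#' @param tol distinctness tolerance
#' @param ... passed to [groebnerBasis()] via [univariateIn()]
#' @return list: `output`, `switchable` (`"yes"`, `"no"`, `"undefined"`),
#'   `rule` (`"cubic-conditions"`, `"repeated-root"`,
#'   `"fallback-comparison"`, `"not-bistable"`), `outputValues` (at the two
#'   stable states), `cubic` (coefficients b, c, d and D when available)
#' @export
outputSwitchable <- function(system, records, verdict, output,
                             solve = NULL, tol = 1e-8, ...) {
  vars <- c(system@variables, names(system@eliminated))
  if (!output %in% vars) stop("unknown output variable: ", output)
  if (!identical(verdict$status, "bistable")) {
    return(list(output = output, switchable = "undefined", rule = "not-bistable",
                outputValues = NULL, cubic = NULL))
  }
  rows <- verdict$countedRows
  stableRows <- rows[records$label[rows] == "stable"]
  unstableRow <- rows[records$label[rows] == "unstable"]
  stableVals <- as.numeric(records[stableRows, output])
  unstableVal <- as.numeric(records[unstableRow, output])
  direct <- abs(stableVals[1] - stableVals[2]) >
    tol * (1 + max(abs(stableVals)))
  # which polynomials define the states: the counted component's polys
  polys <- NULL
  if (output %in% system@variables) {
    comp <- unique(records$component[rows])
    if (!is.null(solve) && length(comp) == 1) {
      compDef <- factorComponents(system)[[comp]]
      polys <- compDef$polys
    } else {
      polys <- steadyStatePolys(system)
    }
  }
  uni <- if (is.null(polys)) NULL else
    univariateIn(polys, output, ...)
  cubic <- NULL
  if (!is.null(uni)) {
    ct <- tryCatch(cubicSwitchTest(uni, var = output),
                   notCubicError = function(e) NULL)
    if (!is.null(ct)) {
      cubic <- ct[c("b", "c", "d", "D")]
      rr <- realRoots(uni, var = output)
      distinctRoots <- nrow(rr) == 3 && all(rr$multiplicity == 1)
      if (ct$pass && distinctRoots) {
        # confirmed against the state solutions (the definition is ground truth)
        return(list(output = output,
                    switchable = if (direct) "yes" else "no",
                    rule = "cubic-conditions",
                    outputValues = stableVals, cubic = cubic))
      }
      rule <- repeatedRootRule(stableVals, unstableVal, tol)
      return(list(output = output,
                  switchable = if (rule$switchable) "yes" else "no",
                  rule = "repeated-root",
                  outputValues = stableVals, cubic = cubic))
    }
    # univariate exists but is not cubic (degree > 3 with inadmissible
    # branches, or below 3): repeated-root rule when roots are scarce,
    # otherwise the direct comparison with the admissible cubic reported
    rr <- realRoots(uni, var = output)
    nAdmissibleVals <- length(unique(round(as.numeric(records[rows, output]), 10)))
    if (nrow(rr) < 3 || any(rr$multiplicity > 1) || nAdmissibleVals < 3) {
      rule <- repeatedRootRule(stableVals, unstableVal, tol)
      return(list(output = output,
                  switchable = if (rule$switchable) "yes" else "no",
                  rule = "repeated-root",
                  outputValues = stableVals, cubic = cubic))
    }
    ac <- admissibleCubic(sort(as.numeric(records[rows, output])))
    ac$D <- cubicDiscriminant(ac$b, ac$c, ac$d)
    cubic <- ac
  } else if (output %in% system@variables || output %in% names(system@eliminated)) {
    # no univariate polynomial in this output: values come from the
    # triangular system computed with a different elimination variable
    if (length(rows) == 3) {
      ac <- admissibleCubic(sort(as.numeric(records[rows, output])))
      ac$D <- cubicDiscriminant(ac$b, ac$c, ac$d)
      cubic <- ac
    }
  }
  list(output = output,
       switchable = if (direct) "yes" else "no",
       rule = "fallback-comparison",
       outputValues = stableVals, cubic = cubic)
}
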