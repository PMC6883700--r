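# Solving the triangular chain: exact real-root isolation of the univariate
# basis polynomial, back-substitution through the chain, and filtering of
# admissible (real, nonnegative, distinct, denominator-nonzero) steady states.

#' Default numeric tolerances of the steady-state solver
#'
#' `root`: relative width of the final isolating interval of a real root;
#' `residual`: residual bound (scaled by 1 + coefficient magnitude) a state
#' must satisfy on every steady-state polynomial; `distinct`: relative
#' infinity-norm gap below which two states are considered identical;
#' `nonneg`: slack for the nonnegativity filter; `imag`: relative
#' imaginary-part cutoff for roots from the numeric fallback path;
#' `den`: minimum denominator magnitude.
#'
#' @return named list of tolerances
#' @export
solverTolerances <- function() {
  list(root = 1e-13, residual = 1e-8, distinct = 1e-8,
       nonneg = 1e-9, imag = 1e-9, den = 1e-9)
}

#' Real roots of a univariate polynomial
#'
#' Exact isolation: Yun squarefree decomposition, Sturm-sequence counting and
#' dyadic bisection, refined to relative width `tol`.  Exact rational roots
#' are detected (by exact evaluation of a continued-fraction reconstruction,
#' or when bisection lands on the root) and reported in the `exact` column.
#'
#' @param p a [QPolynomial] univariate in some variable (or a numeric /
#'   character vector of ascending coefficients)
#' @param tol relative interval-width target
#' @param var variable name when `p` is a [QPolynomial] over several
#'   variables of which only one occurs
#' @return data.frame with columns `value` (double, ascending),
#'   `multiplicity` (integer) and `exact` (rational string or `NA`)
#' @examples
#' p <- qpFromUniCoefs("x", c(0, 12, -8, 1))  # x^3 - 8 x^2 + 12 x
#' realRoots(p)                               # 0, 2, 6
#' @export
realRoots <- function(p, tol = solverTolerances()$root, var = NULL) {
  coefs <- if (is(p, "QPolynomial")) {
    used <- qpVarsUsed(p)
    if (length(used) > 1) stop("polynomial is not univariate")
    v <- if (!is.null(var)) var else if (length(used)) used else p@vars[1]
    qpUniCoefs(p, v)
  } else if (is.numeric(p)) rationalize(format(p, digits = 17)) else as.character(p)
  if (all(vapply(coefs, function(s) cpp_rat_cmp(s, "0") == 0, logical(1))))
    stop("the zero polynomial does not have isolated roots")
  res <- cpp_uni_roots(coefs, tol)
  data.frame(value = res$value,
             multiplicity = res$multiplicity,
             exact = ifelse(nzchar(res$exact), res$exact, NA_character_),
             stringsAsFactors = FALSE)
}

# numeric fallback: roots of a double-coefficient univariate polynomial
.num_uni_roots <- function(coefs, imagTol) {
  scale <- max(abs(coefs))
  if (scale == 0) return(numeric())
  co <- coefs / scale
  while (length(co) > 1 && abs(co[length(co)]) < 1e-14) co <- co[-length(co)]
  if (length(co) <= 1) return(numeric())
  rts <- polyroot(co)
  re <- Re(rts)[abs(Im(rts)) <= imagTol * (1 + abs(Re(rts)))]
  if (!length(re)) return(numeric())
  # Newton polish
  dco <- co[-1] * seq_len(length(co) - 1)
  for (it in 1:8) {
    f <- vapply(re, function(x) sum(co * x^(seq_along(co) - 1)), numeric(1))
    fp <- vapply(re, function(x) sum(dco * x^(seq_along(dco) - 1)), numeric(1))
    step <- ifelse(abs(fp) > 1e-300, f / fp, 0)
    re <- re - step
  }
  sort(re)
}

# numeric coefficients of poly p in variable v, other variables substituted
.uni_coefs_at <- function(p, v, values) {
  j <- match(v, p@vars)
  if (qpIsZero(p)) return(0)
  d <- max(p@exps[, j])
  co <- cpp_rat_to_double(p@coefs)
  x <- as.numeric(values[p@vars])
  x[j] <- 1
  contrib <- co * apply(p@exps, 1, function(e) { e2 <- e; e2[j] <- 0; prod(x^e2) })
  out <- numeric(d + 1)
  for (i in seq_along(contrib)) out[p@exps[i, j] + 1] <- out[p@exps[i, j] + 1] + contrib[i]
  out
}

.poly_scale_num <- function(p) if (qpIsZero(p)) 1 else max(abs(cpp_rat_to_double(p@coefs)))

#' Back-substitute through a triangular chain
#'
#' Extends every root of the univariate basis polynomial through the
#' remaining chain polynomials.  When all previously assigned components are
#' exact rationals the extension is computed exactly (substitution plus exact
#' root isolation); otherwise coefficients are evaluated numerically and
#' roots polished by Newton iteration.  Nonlinear chain elements contribute
#' every real branch; consistency of each partial solution is enforced by a
#' residual check against all chain polynomials at its level, and partial
#' roots with no consistent extension are flagged rather than aborting the
#' solve.
#'
#' @param triangular result of [extractTriangular()]
#' @param tol tolerance list, see [solverTolerances()]
#' @return list of candidate states; each has `values` (named numeric),
#'   `exact` (named character, `NA` where irrational) and `flag`
#'   (`"ok"` or `"no-extension"`)
#' @export
backSubstitute <- function(triangular, tol = solverTolerances()) {
  ranking <- triangular$ranking
  n <- length(ranking)
  chain <- triangular$chain
  solveOrder <- rev(ranking) # univariate variable first
  rr <- realRoots(triangular$univariate, tol$root)
  partials <- lapply(seq_len(nrow(rr)), function(i) {
    list(values = setNames(rr$value[i], solveOrder[1]),
         exact = setNames(rr$exact[i], solveOrder[1]),
         flag = "ok")
  })
  if (n == 1) return(partials)
  for (lev in 2:n) {
    v <- solveOrder[lev]
    known <- solveOrder[1:(lev - 1)]
    cand <- Filter(function(p) {
      used <- qpVarsUsed(p)
      v %in% used && all(used %in% c(known, v))
    }, chain)
    nextPartials <- list()
    for (pa in partials) {
      if (pa$flag != "ok") { nextPartials <- c(nextPartials, list(pa)); next }
      if (!length(cand)) {
        # variable unconstrained at this level: not zero-dimensional
        pa$flag <- "no-extension"
        nextPartials <- c(nextPartials, list(pa))
        next
      }
      degs <- vapply(cand, qpDegreeIn, integer(1), var = v)
      allExact <- !anyNA(pa$exact[known])
      roots <- NULL
      exacts <- NULL
      # try candidates from lowest degree in v upward: a chain element can
      # degenerate (vanish identically) at special partial roots, in which
      # case the next one constrains v
      for (ci in order(degs)) {
        solver <- cand[[ci]]
        if (allExact) {
          sub <- solver
          for (k in known) sub <- qpSubstRat(sub, k, pa$exact[[k]])
          if (qpIsZero(sub)) next                  # degenerate: no information
          if (!length(qpVarsUsed(sub))) {          # nonzero constant: inconsistent
            roots <- numeric()
            break
          }
          rs <- realRoots(sub, tol$root, var = v)
          roots <- rs$value
          exacts <- rs$exact
          break
        } else {
          co <- .uni_coefs_at(solver, v, pa$values)
          scale <- max(abs(co))
          if (scale < 1e-10 * (1 + .poly_scale_num(solver))) next  # degenerate
          if (all(abs(co[-1]) < 1e-12 * scale)) {  # numerically constant, nonzero
            roots <- numeric()
            break
          }
          roots <- .num_uni_roots(co, tol$imag)
          exacts <- rep(NA_character_, length(roots))
          break
        }
      }
      if (is.null(roots) || !length(roots)) {
        pa$flag <- "no-extension"
        nextPartials <- c(nextPartials, list(pa))
        next
      }
      for (ri in seq_along(roots)) {
        values <- c(pa$values, setNames(roots[ri], v))
        exact <- c(pa$exact, setNames(exacts[ri], v))
        # consistency against every candidate polynomial at this level
        ok <- all(vapply(cand, function(p) {
          abs(qpEvalNum(p, values)) <= tol$residual * (1 + .poly_scale_num(p))
        }, logical(1)))
        if (ok) nextPartials <- c(nextPartials, list(list(values = values, exact = exact, flag = "ok")))
      }
    }
    partials <- nextPartials
  }
  partials
}

# Newton polish of a full state on the (square) steady-state system
.polish_state <- function(values, polys, vars) {
  x <- as.numeric(values[vars])
  for (it in 1:20) {
    f <- vapply(polys, qpEvalNum, numeric(1), point = setNames(x, vars))
    if (max(abs(f)) < 1e-14 * (1 + max(abs(x)))) break
    J <- matrix(0, length(polys), length(vars))
    for (i in seq_along(polys)) for (j in seq_along(vars)) {
      J[i, j] <- qpEvalNum(qpDeriv(polys[[i]], vars[j]), setNames(x, vars))
    }
    step <- tryCatch(qr.solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    if (max(abs(step)) > 1 + max(abs(x))) break
    x <- x - step
  }
  setNames(x, vars)
}

#' Admissibility filter for candidate steady states
#'
#' Keeps states whose components are all nonnegative (within slack),
#' pairwise distinct, with every right-hand-side denominator bounded away
#' from zero, and whose eliminated conserved species (reconstructed from the
#' recorded constraints) are nonnegative as well.  Rejected states stay in
#' the output with a reason code.
#'
#' @param states list of states from [backSubstitute()]
#' @param system the [RationalODESystem] being solved
#' @param tol tolerance list, see [solverTolerances()]
#' @return data.frame with one row per candidate: one column per variable
#'   (including eliminated species), `admissible`, `reason`
#' @export
admissibleFilter <- function(states, system, tol = solverTolerances()) {
  vars <- system@variables
  elimVars <- names(system@eliminated)
  allVars <- c(vars, elimVars)
  rows <- list()
  for (st in states) {
    reason <- ""
    if (st$flag != "ok") reason <- "inconsistent-chain"
    vals <- st$values[vars]
    exact <- st$exact[vars]
    # polish numerically unless fully exact
    if (anyNA(exact) && reason == "") {
      vals <- .polish_state(vals, steadyStatePolys(system), vars)
    }
    full <- vals
    for (ev in elimVars) {
      expr <- system@eliminated[[ev]]
      evVal <- if (!anyNA(exact)) {
        cpp_rat_to_double(qpEvalRat(expr, setNames(exact, vars)))
      } else qpEvalNum(expr, vals)
      full <- c(full, setNames(evVal, ev))
    }
    if (reason == "" && any(full < -tol$nonneg * (1 + abs(full)) - tol$nonneg))
      reason <- "negative-component"
    if (reason == "") {
      denOk <- all(vapply(system@denominators, function(d)
        abs(qpEvalNum(d, vals)) > tol$den, logical(1)))
      if (!denOk) reason <- "denominator-zero"
    }
    if (reason == "") {
      resid <- vapply(steadyStatePolys(system), function(p)
        abs(qpEvalNum(p, vals)) / (1 + .poly_scale_num(p)), numeric(1))
      if (max(resid) > tol$residual) reason <- "residual"
    }
    rows[[length(rows) + 1]] <- list(full = full, exact = st$exact,
                                     admissible = reason == "", reason = reason)
  }
  # pairwise distinctness among admissible states
  if (length(rows) > 1) {
    for (i in seq_along(rows)) {
      if (!rows[[i]]$admissible) next
      for (j in seq_len(i - 1)) {
        if (!rows[[j]]$admissible) next
        a <- rows[[i]]$full
        b <- rows[[j]]$full
        if (max(abs(a - b)) <= tol$distinct * (1 + max(abs(a)))) {
          rows[[i]]$admissible <- FALSE
          rows[[i]]$reason <- "duplicate"
          break
        }
      }
    }
  }
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r) r$full)))
  names(df) <- allVars
  df$admissible <- vapply(rows, `[[`, logical(1), "admissible")
  df$reason <- vapply(rows, `[[`, character(1), "reason")
  df$exact <- I(lapply(rows, `[[`, "exact"))
  df
}

#' Solve all steady states of a system
#'
#' Runs the full elimination pipeline: factor-component enumeration (for
#' systems with variable factors such as `Y * h = 0`), reduced lex Groebner
#' basis per component, triangular extraction, exact/numeric
#' back-substitution and admissibility filtering.  States found on boundary
#' components (where a factored variable is pinned to zero) are tagged.
#'
#' @param system a [RationalODESystem]
#' @param ranking lex ranking (highest first); default: declared variable
#'   order (so the univariate element lives in the last variable)
#' @param tol tolerance list, see [solverTolerances()]
#' @param backend Groebner backend, see [groebnerBasis()]
#' @param pairCap resource guard for the internal engine
#' @return list with `states` (data.frame as in [admissibleFilter()], plus
#'   `component` and `boundary` columns), `basis` (the core component's
#'   [GroebnerBasisResult]) and `components` (per-component details)
#' @export
solveSteadyStates <- function(system, ranking = NULL, tol = solverTolerances(),
                              backend = "internal", pairCap = 20000) {
  if (is.null(ranking)) ranking <- system@variables
  meta <- system@metadata
  comps <- factorComponents(system)
  compRes <- list()
  stateTabs <- list()
  coreBasis <- NULL
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    gb <- groebnerBasis(comp$polys, ranking, backend = backend, pairCap = pairCap)
    tri <- tryCatch(extractTriangular(gb), switchscanError = function(e) e)
    if (inherits(tri, "error")) {
      compRes[[ci]] <- list(basis = gb, error = conditionMessage(tri),
                            boundary = comp$boundary)
      next
    }
    states <- backSubstitute(tri, tol)
    tab <- admissibleFilter(states, system, tol)
    if (nrow(tab)) {
      tab$component <- ci
      tab$boundary <- comp$boundary
    }
    stateTabs[[length(stateTabs) + 1]] <- tab
    compRes[[ci]] <- list(basis = gb, triangular = tri, boundary = comp$boundary)
    if (!comp$boundary && is.null(coreBasis)) coreBasis <- gb
  }
  if (is.null(coreBasis) && length(compRes)) coreBasis <- compRes[[1]]$basis
  states <- if (length(stateTabs)) do.call(rbind, stateTabs) else
    data.frame()
  # cross-component duplicates: keep the non-boundary copy
  if (nrow(states) > 1) {
    vars <- c(system@variables, names(system@eliminated))
    keep <- rep(TRUE, nrow(states))
    ordIdx <- order(states$boundary) # non-boundary first
    for (a in seq_along(ordIdx)) {
      i <- ordIdx[a]
      if (!keep[i] || !states$admissible[i]) next
      for (b in seq_len(a - 1)) {
        j <- ordIdx[b]
        if (!keep[j] || !states$admissible[j]) next
        d <- max(abs(as.numeric(states[i, vars]) - as.numeric(states[j, vars])))
        if (d <= tol$distinct * (1 + max(abs(as.numeric(states[i, vars]))))) {
          keep[i] <- FALSE
          break
        }
      }
    }
    states <- states[keep, , drop = FALSE]
    rownames(states) <- NULL
  }
  list(states = states, basis = coreBasis, components = compRes, ranking = ranking)
}
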