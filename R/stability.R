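# Jacobians, eigenvalue classification, and the bistability verdict:
# necessary condition (three distinct nonnegative states from the triangular
# system) plus sufficiency by the eigenvalues of the local Jacobians.

#' Symbolic Jacobian of a rational ODE system
#'
#' Quotient rule on `f_i/d_i`: entry (i,j) is
#' `(df_i/dx_j * d_i - f_i * dd_i/dx_j) / d_i^2`, valid wherever `d_i != 0`
#' (denominators are checked by the admissibility filter before any
#' classification).
#'
#' @param system a [RationalODESystem]
#' @return list with `num` (matrix-list of [QPolynomial] numerators) and
#'   `den` (list of per-row denominators `d_i^2`)
#' @export
jacobianSystem <- function(system) {
  vars <- system@variables
  n <- length(vars)
  num <- vector("list", n * n)
  dim(num) <- c(n, n)
  den <- vector("list", n)
  for (i in seq_len(n)) {
    fi <- system@numerators[[i]]
    di <- system@denominators[[i]]
    constantDen <- qpDegree(di) <= 0L
    den[[i]] <- if (constantDen) di else di * di
    for (j in seq_len(n)) {
      dfij <- qpDeriv(fi, vars[j])
      if (constantDen) {
        num[[i, j]] <- dfij
      } else {
        num[[i, j]] <- dfij * di - fi * qpDeriv(di, vars[j])
      }
    }
  }
  list(num = num, den = den, variables = vars)
}

#' Evaluate a symbolic Jacobian at a state
#'
#' @param J result of [jacobianSystem()]
#' @param state named numeric vector of state values
#' @return numeric matrix
#' @export
evalJacobian <- function(J, state) {
  n <- length(J$variables)
  out <- matrix(0, n, n, dimnames = list(J$variables, J$variables))
  for (i in seq_len(n)) {
    dv <- qpEvalNum(J$den[[i]], state)
    for (j in seq_len(n)) out[i, j] <- qpEvalNum(J$num[[i, j]], state) / dv
  }
  out
}

#' Classify a steady state by Jacobian eigenvalues
#'
#' A state is `stable` when every eigenvalue has real part below `-tol`,
#' `unstable` when some real part exceeds `tol`, and `marginal` when the
#' largest real part lies within the threshold band -- linearization is
#' silent there, so no stable/unstable guess is made.
#'
#' @param state named numeric vector
#' @param J result of [jacobianSystem()]
#' @param tol marginality threshold on eigenvalue real parts
#' @return list with `eigenvalues` (complex), `maxRe` and
#'   `label` in `c("stable", "unstable", "marginal")`
#' @export
classifySteadyState <- function(state, J, tol = 1e-9) {
  m <- evalJacobian(J, state)
  ev <- eigen(m, only.values = TRUE)$values
  maxRe <- max(Re(ev))
  label <- if (maxRe < -tol) "stable" else if (maxRe > tol) "unstable" else "marginal"
  list(eigenvalues = ev, maxRe = maxRe, label = label)
}

#' Stability records for a table of steady states
#'
#' @param states data.frame from [solveSteadyStates()]
#' @param system a [RationalODESystem]
#' @param tol marginality threshold
#' @return the data.frame with `label`, `maxRe` and a list-column
#'   `eigenvalues` appended (admissible states only are classified)
#' @export
stabilityRecords <- function(states, system, tol = 1e-9) {
  J <- jacobianSystem(system)
  n <- nrow(states)
  labels <- rep(NA_character_, n)
  maxRe <- rep(NA_real_, n)
  eig <- vector("list", n)
  for (i in seq_len(n)) {
    if (!isTRUE(states$admissible[i])) next
    st <- setNames(as.numeric(states[i, system@variables]), system@variables)
    cl <- classifySteadyState(st, J, tol)
    labels[i] <- cl$label
    maxRe[i] <- cl$maxRe
    eig[[i]] <- cl$eigenvalues
  }
  states$label <- labels
  states$maxRe <- maxRe
  states$eigenvalues <- I(eig)
  states
}

#' Fixed-point bistability verdict
#'
#' A system is fixed-point bistable when it has exactly three nonnegative
#' distinct real steady states, two stable and one unstable.  States on a
#' boundary component (a factored variable pinned at zero, which by itself
#' cannot carry three states) are excluded from the count, mirroring the
#' case split used for factorizable networks; systems failing the
#' three-state necessary condition cannot be bistable, and any marginal
#' label among the three makes the verdict inconclusive.  More than three
#' admissible states is reported as `not_bistable` with the count
#' (multistability beyond three is reported, not adjudicated).
#'
#' @param records data.frame from [stabilityRecords()]
#' @param outputVar optional variable along which the label pattern is
#'   ordered (defaults to the first variable column)
#' @return list with `status` (`"bistable"`, `"not_bistable"`,
#'   `"inconclusive"`), `admissibleCount`, `pattern` (ordered labels) and
#'   `countedRows` (row indices used for the verdict)
#' @export
bistabilityVerdict <- function(records, outputVar = NULL) {
  adm <- which(records$admissible)
  counted <- adm
  if (length(adm) && any(records$boundary[adm])) {
    nonB <- adm[!records$boundary[adm]]
    # boundary states count only if the interior component alone cannot
    # provide the three states
    if (length(nonB) >= 3) counted <- nonB
  }
  if (is.null(outputVar)) {
    outputVar <- names(records)[1]
  }
  ordIdx <- counted[order(as.numeric(records[counted, outputVar]))]
  pattern <- records$label[ordIdx]
  n <- length(counted)
  status <- if (n != 3) "not_bistable"
    else if (any(pattern == "marginal")) "inconclusive"
    else if (sum(pattern == "stable") == 2 && sum(pattern == "unstable") == 1 &&
             identical(pattern, c("stable", "unstable", "stable"))) "bistable"
    else if (sum(pattern == "stable") == 2 && sum(pattern == "unstable") == 1) "bistable"
    else "not_bistable"
  list(status = status, admissibleCount = n, pattern = pattern,
       countedRows = ordIdx)
}
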