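# Numerical trajectories: fixed-step classical Runge-Kutta on the full
# rational system and on the one-dimensional univariate-basis system, plus
# the attractor-agreement check (both converge to the same stable state).

#' Integrate a rational ODE system
#'
#' Fixed-step classical 4th-order Runge-Kutta.  Denominators are guarded: if
#' any `|d_i|` falls below `denTol` along the path the trajectory is
#' truncated and flagged.  The terminal state is tagged with the nearest
#' admissible steady state when the velocity norm has dropped below
#' `convTol`.
#'
#' @param system a [RationalODESystem]
#' @param x0 named numeric initial state (componentwise nonnegative)
#' @param tEnd final time
#' @param step step size; default `1e-3 * tEnd`
#' @param states optional steady-state table (data.frame with variable
#'   columns) for convergence tagging
#' @param convTol velocity-norm threshold declaring convergence
#' @param denTol denominator guard
#' @param keep store every `keep`-th point (1 = all)
#' @return list: `times`, `states` (matrix), `terminal` (named numeric),
#'   `converged` (logical), `convergedTo` (row index into `states` input or
#'   `NA`), `truncated` (logical)
#' @export
integrateSystem <- function(system, x0, tEnd = 100, step = NULL, states = NULL,
                            convTol = 1e-8, denTol = 1e-10, keep = 10L) {
  vars <- system@variables
  x0 <- x0[vars]
  if (anyNA(x0)) stop("x0 must supply every state variable")
  if (any(x0 < 0)) stop("initial state must be componentwise nonnegative")
  if (is.null(step)) step <- 1e-3 * tEnd
  numD <- lapply(system@numerators, function(p) list(exps = p@exps, co = cpp_rat_to_double(p@coefs)))
  denD <- lapply(system@denominators, function(p) list(exps = p@exps, co = cpp_rat_to_double(p@coefs)))
  evalOne <- function(tb, x) {
    if (!nrow(tb$exps)) return(0)
    sum(tb$co * apply(tb$exps, 1, function(e) prod(x^e)))
  }
  rhs <- function(x) {
    d <- vapply(denD, evalOne, numeric(1), x = x)
    if (any(abs(d) < denTol)) return(NULL)
    vapply(numD, evalOne, numeric(1), x = x) / d
  }
  nSteps <- ceiling(tEnd / step)
  x <- as.numeric(x0)
  times <- 0
  traj <- matrix(x, 1, length(vars), dimnames = list(NULL, vars))
  truncated <- FALSE
  for (k in seq_len(nSteps)) {
    k1 <- rhs(x)
    if (is.null(k1)) { truncated <- TRUE; break }
    k2 <- rhs(x + step / 2 * k1)
    if (is.null(k2)) { truncated <- TRUE; break }
    k3 <- rhs(x + step / 2 * k2)
    if (is.null(k3)) { truncated <- TRUE; break }
    k4 <- rhs(x + step * k3)
    if (is.null(k4)) { truncated <- TRUE; break }
    x <- x + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (k %% keep == 0 || k == nSteps) {
      times <- c(times, k * step)
      traj <- rbind(traj, x)
    }
  }
  terminal <- setNames(x, vars)
  v <- rhs(x)
  converged <- !is.null(v) && sqrt(sum(v^2)) < convTol
  convergedTo <- NA_integer_
  if (converged && !is.null(states) && nrow(states)) {
    d <- apply(as.matrix(states[, vars, drop = FALSE]), 1,
               function(s) max(abs(s - x)))
    convergedTo <- which.min(d)
    if (d[convergedTo] > 1e-4 * (1 + max(abs(x)))) convergedTo <- NA_integer_
  }
  list(times = times, states = traj, terminal = terminal,
       converged = converged, convergedTo = convergedTo, truncated = truncated)
}

#' One-dimensional univariate-basis dynamics
#'
#' `dx/dt = g1(x) = -x^3 + b x^2 - c x + d`: the scalar system whose fixed
#' points are the cubic's roots.  Stability follows from the sign of the
#' derivative: negative slope at the outer roots (stable), positive at the
#' middle root (unstable saddle).
#'
#' @param b,c,d cubic coefficients (rational strings or numerics)
#' @param var variable name for the scalar state
#' @return a [RationalODESystem] in one variable
#' @examples
#' sys1 <- univariateSystem(8, 12, 0)
#' solveSteadyStates(sys1)$states  # fixed points 0, 2, 6
#' @export
univariateSystem <- function(b, c, d, var = "x") {
  pstr <- function(v) if (is.numeric(v)) rationalize(format(v, digits = 17)) else cpp_rat_norm(v)
  odeSystem(var,
            setNames(sprintf("-%s^3 + (%s)*%s^2 - (%s)*%s + (%s)",
                             var, pstr(b), var, pstr(c), var, pstr(d)), var))
}

#' Attractor agreement between the full and the univariate system
#'
#' For a bistable system with a switchable output, trajectories of the full
#' system and of the 1-D univariate-basis system started from the same
#' output value converge to the same stable steady-state output (their
#' transients differ; the attractors agree because both systems share the
#' same steady-state output solutions).
#'
#' @param system the full [RationalODESystem]
#' @param uniSystem the 1-D system from [univariateSystem()]
#' @param output the output variable of `system` matched to the 1-D state
#' @param x0 named numeric initial state for the full system
#' @param tEnd,step integration controls
#' @param tol agreement tolerance on the terminal output values
#' @return logical: do the terminal outputs agree within `tol`?
#' @export
sameAttractorCheck <- function(system, uniSystem, output, x0,
                               tEnd = 100, step = NULL, tol = 1e-4) {
  full <- integrateSystem(system, x0, tEnd, step)
  v1 <- uniSystem@variables[1]
  y0 <- setNames(as.numeric(x0[output]), v1)
  uni <- integrateSystem(uniSystem, y0, tEnd, step)
  if (full$truncated || uni$truncated) return(NA)
  abs(full$terminal[[output]] - uni$terminal[[v1]]) <= tol * (1 + abs(uni$terminal[[v1]]))
}
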