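# Model construction: mass-action ODEs from reaction networks, explicit
# rational ODEs, conservation-law elimination, denominator clearing.

#' Define a reaction
#'
#' @param reactants named integer vector (species -> stoichiometry); empty for
#'   a zeroth-order source such as a constant inflow
#' @param products named integer vector (possibly empty for pure degradation)
#' @param k rate constant: a parameter name, or a rational/numeric literal
#' @param label optional text label
#' @return a reaction record (list)
#' @examples
#' reaction(c(Y = 1), c(X = 2), k = "k1")          # Y -> 2X
#' reaction(integer(), c(Z = 1), k = "v")          # 0 -> Z (constant inflow)
#' @export
reaction <- function(reactants, products, k, label = "") {
  reactants <- unlist(reactants)
  products <- unlist(products)
  if (length(reactants) && (is.null(names(reactants)) || any(!nzchar(names(reactants)))))
    stop("reactants must be a named vector")
  if (length(products) && (is.null(names(products)) || any(!nzchar(names(products)))))
    stop("products must be a named vector")
  list(reactants = as.list(reactants), products = as.list(products),
       k = as.character(k), label = label)
}

#' Assemble a reaction network
#'
#' @param species character vector of dynamic species
#' @param reactions list of [reaction()] records
#' @param parameters named vector of rate-constant values (rational strings or
#'   numerics)
#' @param fixed character vector of clamped species (inert products, lumped
#'   reactants); they may appear in reactions but get no ODE
#' @param snap optional snap table (see [rationalize()])
#' @return a [ReactionNetwork]
#' @export
reactionNetwork <- function(species, reactions, parameters = character(),
                            fixed = character(), snap = NULL) {
  params <- if (length(parameters))
    setNames(rationalize(as.character(parameters), snap), names(parameters))
  else character()
  nw <- new("ReactionNetwork", species = species, fixed = fixed,
            reactions = reactions, parameters = params)
  validObject(nw)
  nw
}

#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species)

#' @export
setMethod("reactions", "ReactionNetwork", function(x) x@reactions)

#' @export
setMethod("parameters", "ReactionNetwork", function(x) x@parameters)

setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork:", length(object@species), "species,",
      length(object@reactions), "reactions\n")
  fmtSide <- function(side) {
    if (!length(side)) return("0")
    paste(vapply(names(side), function(s) {
      n <- side[[s]]
      if (n == 1) s else paste0(n, " ", s)
    }, character(1)), collapse = " + ")
  }
  for (r in object@reactions) {
    cat("  ", fmtSide(r$reactants), " --", r$k, "--> ", fmtSide(r$products), "\n", sep = "")
  }
})

.resolve_rate <- function(k, params) {
  if (k %in% names(params)) return(params[[k]])
  out <- tryCatch(cpp_rat_norm(k), error = function(e) NULL)
  if (is.null(out)) stop("rate constant '", k, "' is neither a parameter nor a literal")
  out
}

#' Mass-action ODE system of a reaction network
#'
#' For each dynamic species `s` the right-hand side is the stoichiometric sum
#' over reactions, `sum (Delta_s) * k * prod(reactant^stoich)`, with fixed
#' (clamped) species contributing neither concentration factors nor ODEs --
#' their levels are folded into the rate constants.  A reaction with an empty
#' reactant map is a zeroth-order source with constant rate `k`.
#'
#' @param network a [ReactionNetwork]
#' @return a [RationalODESystem] with all denominators equal to 1
#' @examples
#' # the minimal bistable network: S+Y -> 2X, 2X -> X+Y, X+Y -> Y+P, X -> P
#' nw <- reactionNetwork(
#'   species = c("x", "y"), fixed = c("P"),
#'   reactions = list(
#'     reaction(c(y = 1), c(x = 2), "k1"),
#'     reaction(c(x = 2), c(x = 1, y = 1), "k2"),
#'     reaction(c(x = 1, y = 1), c(y = 1, P = 1), "k3"),
#'     reaction(c(x = 1), c(P = 1), "k4")),
#'   parameters = c(k1 = 8, k2 = 1, k3 = 1, k4 = 1.5))
#' massActionOdes(nw)
#' @export
massActionOdes <- function(network) {
  vars <- network@species
  zero <- qpoly(vars)
  one <- qpConst(vars, "1")
  num <- rep(list(zero), length(vars))
  names(num) <- vars
  for (r in network@reactions) {
    k <- .resolve_rate(r$k, network@parameters)
    if (cpp_rat_cmp(k, "0") <= 0)
      stop("nonpositive rate constant for reaction '", r$k, "'")
    # rate monomial: k * prod over dynamic reactants
    e <- matrix(0L, 1, length(vars))
    for (s in names(r$reactants)) {
      j <- match(s, vars)
      if (!is.na(j)) e[1, j] <- e[1, j] + as.integer(r$reactants[[s]])
    }
    rate <- qpoly(vars, e, k)
    delta <- setNames(rep(0L, length(vars)), vars)
    for (s in names(r$reactants)) if (s %in% vars) delta[s] <- delta[s] - as.integer(r$reactants[[s]])
    for (s in names(r$products)) if (s %in% vars) delta[s] <- delta[s] + as.integer(r$products[[s]])
    for (v in vars) {
      if (delta[v] != 0L) num[[v]] <- num[[v]] + qpConst(vars, as.character(delta[v])) * rate
    }
  }
  sys <- new("RationalODESystem",
             variables = vars,
             numerators = unname(num),
             denominators = rep(list(one), length(vars)),
             parameters = network@parameters,
             constraintList = list(),
             eliminated = list(),
             definition = list(kind = "reactions", network = network),
             metadata = list())
  validObject(sys)
  sys
}

#' Define a conservation constraint
#'
#' @param coefficients named vector of rational coefficients (one per
#'   variable involved)
#' @param total the conserved total (rational string or numeric)
#' @param victim variable to eliminate; `NA` chooses the constraint variable
#'   with the largest index in the system's variable order
#' @return a [ConservationConstraint]
#' @export
conservationConstraint <- function(coefficients, total, victim = NA_character_) {
  cc <- new("ConservationConstraint",
            coefficients = setNames(rationalize(as.character(coefficients)),
                                    names(coefficients)),
            total = rationalize(as.character(total)),
            victim = as.character(victim))
  validObject(cc)
  cc
}

#' Eliminate a conserved variable
#'
#' Substitutes `victim = (total - sum(other terms)) / coef(victim)` into every
#' right-hand side, drops the victim's ODE, and records the linear expression
#' so that the eliminated species can be reconstructed (and checked for
#' nonnegativity) for every reported steady state.
#'
#' @param system a [RationalODESystem]
#' @param constraint a [ConservationConstraint]
#' @param victim variable to eliminate; default: the constraint's declared
#'   victim, else the constraint variable with the largest index in the
#'   system's variable order
#' @return the reduced [RationalODESystem]
#' @export
eliminateConserved <- function(system, constraint, victim = NULL) {
  vars <- system@variables
  cvars <- names(constraint@coefficients)
  if (is.null(victim)) {
    victim <- if (!is.na(constraint@victim)) constraint@victim
      else {
        present <- intersect(vars, cvars)
        if (!length(present)) cvars[length(cvars)] else present[length(present)]
      }
  }
  if (!victim %in% cvars)
    stop("victim '", victim, "' does not appear in the constraint")
  cv <- constraint@coefficients[[victim]]
  if (cpp_rat_cmp(cv, "0") == 0)
    stop("victim '", victim, "' has zero coefficient in the constraint")
  if (!victim %in% vars) {
    # bookkeeping only: the system does not contain the victim
    system@constraintList <- c(system@constraintList, list(constraint))
    return(system)
  }
  # expression for the victim over the remaining variables
  keep <- setdiff(vars, victim)
  expr <- qpConst(vars, cpp_rat_arith("div", constraint@total, cv))
  for (v in setdiff(cvars, victim)) {
    if (!v %in% vars)
      stop("constraint variable '", v, "' is not a system variable")
    coefOver <- cpp_rat_arith("div", constraint@coefficients[[v]], cv)
    expr <- expr - qpConst(vars, coefOver) * qpVar(vars, v)
  }
  dropCol <- function(p) {
    j <- match(victim, p@vars)
    if (!qpIsZero(p) && any(p@exps[, j] > 0))
      stop("internal error: victim still present after substitution")
    new("QPolynomial", vars = keep,
        exps = p@exps[, -j, drop = FALSE], coefs = p@coefs)
  }
  idx <- match(victim, vars)
  num <- lapply(system@numerators[-idx], function(p) dropCol(qpSubstPoly(p, victim, expr)))
  den <- lapply(system@denominators[-idx], function(p) dropCol(qpSubstPoly(p, victim, expr)))
  elim <- system@eliminated
  # previously eliminated expressions may mention the victim: substitute there too
  elim <- lapply(elim, function(p) dropCol(qpSubstPoly(p, victim, expr)))
  elim[[victim]] <- dropCol(expr)
  out <- new("RationalODESystem",
             variables = keep, numerators = num, denominators = den,
             parameters = system@parameters,
             constraintList = c(system@constraintList, list(constraint)),
             eliminated = elim,
             definition = system@definition,
             metadata = system@metadata)
  validObject(out)
  out
}

#' Build a rational ODE system from expressions
#'
#' Expressions are parsed with exact rational arithmetic and their
#' denominators cleared into numerator/denominator polynomial pairs
#' (`dx/dt = f_i/d_i`); steady-state analysis solves `f_i = 0` and checks
#' `d_i != 0` a posteriori.  Variables without an expression must be covered
#' by a conservation constraint and are eliminated at construction.
#'
#' @param variables ordered character vector of state variables
#' @param odes named character vector/list of right-hand-side expressions
#' @param parameters named vector of parameter values
#' @param constraints list of [ConservationConstraint]
#' @param snap optional snap table (see [rationalize()])
#' @return a [RationalODESystem]
#' @examples
#' odeSystem(c("x", "y"),
#'           c(x = "16*y - x^2 - x*y - 1.5*x", y = "x^2 - 8*y"))
#' @export
odeSystem <- function(variables, odes, parameters = character(),
                      constraints = list(), snap = NULL) {
  params <- if (length(parameters))
    setNames(as.character(parameters), names(parameters))
  else character()
  missingOde <- setdiff(variables, names(odes))
  rf <- lapply(variables, function(v) {
    if (v %in% names(odes))
      parseRationalExpression(odes[[v]], variables, params, snap)
    else
      .rf_const(variables, "0") # placeholder; variable gets eliminated below
  })
  sys <- new("RationalODESystem",
             variables = variables,
             numerators = lapply(rf, `[[`, "num"),
             denominators = lapply(rf, `[[`, "den"),
             parameters = setNames(rationalize(unname(params), snap), names(params)),
             constraintList = list(),
             eliminated = list(),
             definition = list(kind = "odes", variables = variables, odes = odes,
                               parameters = params, constraints = constraints,
                               snap = snap),
             metadata = list())
  # algebraic variables: eliminate through the constraint that contains them
  for (v in missingOde) {
    found <- FALSE
    for (cc in constraints) {
      vict <- if (!is.na(cc@victim)) cc@victim else NULL
      if ((is.null(vict) && v %in% names(cc@coefficients)) || identical(vict, v)) {
        sys <- eliminateConserved(sys, cc, victim = v)
        constraints <- constraints[!vapply(constraints, identical, logical(1), cc)]
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("variable '", v, "' has neither an ODE nor a covering constraint")
  }
  for (cc in constraints) sys <- eliminateConserved(sys, cc)
  validObject(sys)
  sys
}

#' Clear denominators of rational rate expressions
#'
#' Converts a list of rational right-hand-side expressions to an exact
#' numerator/denominator system: `expr_i = f_i / d_i` with no common
#' polynomial factor between the pair (full cancellation is attempted by
#' exact division and monomial-content stripping).
#'
#' @inheritParams odeSystem
#' @param exprs named character vector of rational expressions, one per
#'   variable
#' @return a [RationalODESystem]
#' @export
clearDenominators <- function(exprs, variables = names(exprs),
                              parameters = character(), snap = NULL) {
  odeSystem(variables, exprs, parameters, constraints = list(), snap = snap)
}

#' @export
setMethod("variables", "RationalODESystem", function(x) x@variables)

#' @export
setMethod("parameters", "RationalODESystem", function(x) x@parameters)

#' @export
setMethod("rhsNumerators", "RationalODESystem", function(x) x@numerators)

#' @export
setMethod("rhsDenominators", "RationalODESystem", function(x) x@denominators)

#' @export
setMethod("constraints", "RationalODESystem", function(x) x@constraintList)

setMethod("show", "RationalODESystem", function(object) {
  cat("RationalODESystem with", length(object@variables), "state variable(s):",
      paste(object@variables, collapse = ", "), "\n")
  for (i in seq_along(object@variables)) {
    d <- object@denominators[[i]]
    rhs <- formatPoly(object@numerators[[i]])
    if (qpDegree(d) > 0L || !identical(d@coefs, "1"))
      rhs <- paste0("(", rhs, ") / (", formatPoly(d), ")")
    cat("  d", object@variables[i], "/dt = ", rhs, "\n", sep = "")
  }
  if (length(object@eliminated)) {
    cat("  eliminated:",
        paste(vapply(names(object@eliminated), function(v)
          paste0(v, " = ", formatPoly(object@eliminated[[v]])), character(1)),
          collapse = "; "), "\n")
  }
})

#' Rebuild a system with a modified parameter
#'
#' Uses the symbolic definition captured at construction; needed by the
#' bifurcation scan, which re-runs the exact pipeline for every parameter
#' value.
#'
#' @param system a [RationalODESystem] built by [odeSystem()],
#'   [massActionOdes()] or [loadFixture()]
#' @param name parameter name
#' @param value new value (rational string or numeric)
#' @return a rebuilt [RationalODESystem]
#' @export
withParameter <- function(system, name, value) {
  def <- system@definition
  if (!length(def)) stop("system carries no symbolic definition; cannot rescan")
  value <- as.character(value)
  if (identical(def$kind, "odes")) {
    if (!name %in% names(def$parameters))
      stop("parameter '", name, "' does not occur in the model")
    def$parameters[[name]] <- value
    out <- odeSystem(def$variables, def$odes, def$parameters, def$constraints, def$snap)
  } else if (identical(def$kind, "reactions")) {
    nw <- def$network
    if (!name %in% names(nw@parameters))
      stop("parameter '", name, "' does not occur in the model")
    nw@parameters[[name]] <- rationalize(value)
    out <- massActionOdes(nw)
  } else stop("unknown definition kind")
  out@metadata <- system@metadata
  out
}

#' Steady-state polynomial system
#'
#' The polynomials whose common zeros are the steady states: the rhs
#' numerators `f_i` (denominator-cleared).
#'
#' @param system a [RationalODESystem]
#' @return list of [QPolynomial]
#' @export
steadyStatePolys <- function(system) system@numerators

# variable factors of the numerators, e.g. Y * h(X,Y,Z): each equation
# splits into its monomial variable factors plus the core polynomial.
.equation_factors <- function(p) {
  if (qpIsZero(p)) return(list())
  minExp <- apply(p@exps, 2, min)
  factors <- list()
  for (j in which(minExp > 0)) {
    factors <- c(factors, list(qpVar(p@vars, p@vars[j])))
  }
  core <- p
  if (any(minExp > 0)) {
    core@exps <- sweep(core@exps, 2, minExp)
    core <- .qp_canon(core)
  }
  c(factors, list(core))
}

#' Irreducible-component candidates from variable factors
#'
#' Mass-action systems often factor as `x * h(x) = 0` (an extinction boundary
#' times an interior component, as in networks where a species can be
#' absent).  Each equation is split into its variable factors and its core;
#' the Cartesian product of the choices enumerates the candidate components,
#' which are analyzed separately and merged.
#'
#' @param system a [RationalODESystem]
#' @return list of components, each a list with `polys` (list of
#'   [QPolynomial]) and `boundary` (logical: does it set some variable to 0?)
#' @export
factorComponents <- function(system) {
  choices <- lapply(steadyStatePolys(system), .equation_factors)
  grid <- expand.grid(lapply(choices, seq_along))
  comps <- list()
  seen <- character()
  for (r in seq_len(nrow(grid))) {
    polys <- lapply(seq_along(choices), function(i) choices[[i]][[grid[r, i]]])
    key <- paste(vapply(polys, function(p) paste(formatPoly(p)), character(1)), collapse = " | ")
    if (key %in% seen) next
    seen <- c(seen, key)
    boundary <- any(vapply(seq_along(choices), function(i)
      grid[r, i] < length(choices[[i]]), logical(1)))
    comps[[length(comps) + 1]] <- list(polys = polys, boundary = boundary)
  }
  comps
}

#' Check a conservation constraint structurally
#'
#' A constraint `sum(coef_i x_i) = c` is structural when the corresponding
#' weighted sum of right-hand sides is the zero polynomial (the stoichiometry
#' itself conserves the moiety); otherwise the constraint only holds for
#' special initial conditions and is flagged non-structural.
#'
#' @param system a [RationalODESystem] (mass-action: constant denominators)
#' @param constraint a [ConservationConstraint] over the system's variables
#' @return logical: is the weighted rhs sum identically zero?
#' @export
isStructuralConservation <- function(system, constraint) {
  vars <- system@variables
  acc <- qpoly(vars)
  for (v in names(constraint@coefficients)) {
    i <- match(v, vars)
    if (is.na(i)) return(FALSE)
    if (qpDegree(system@denominators[[i]]) > 0L)
      stop("structural check requires polynomial (cleared) right-hand sides")
    dc <- system@denominators[[i]]@coefs[1]
    term <- qpConst(vars, cpp_rat_arith("div", constraint@coefficients[[v]], dc)) *
      system@numerators[[i]]
    acc <- acc + term
  }
  qpIsZero(acc)
}
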