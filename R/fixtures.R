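# Model JSON reader and the packaged fixtures.

#' Names of the packaged fixture models
#'
#' @return character vector
#' @export
listFixtures <- function() {
  dir <- system.file("extdata", "models", package = "switchscan")
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

#' Read a model definition from JSON
#'
#' The model dialect:
#' \preformatted{
#' {"name": ..., "variables": [...],
#'  "parameters": {sym: "rational-or-decimal"},
#'  "derived":   {sym: "expression in parameters"},          # optional
#'  "snap":      {"0.166": "1/6"},                           # optional
#'  one of
#'  "reactions": [{"reactants": {...}, "products": {...}, "k": "sym"}] (+ "fixed")
#'  or
#'  "odes":      {var: "expression"},
#'  "constraints": [{"coeffs": {var: "rational-or-expr"},
#'                   "total": "rational", "victim": var}],   # optional
#'  "outputs": [...], "order": [...],
#'  "scan": {"parameter": sym, "lo": num, "hi": num}}        # optional
#' }
#' Variables without an ODE must be covered by a constraint and are
#' eliminated at load time.  All literals become exact rationals, with the
#' snap table applied first (printed roundings mapped back to their declared
#' exact values, e.g. 0.166 -> 1/6).
#'
#' @param path path to a model JSON file
#' @return a [RationalODESystem] with `metadata` carrying name, outputs,
#'   preferred lex order and scan window
#' @export
readModel <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  snap <- if (length(m$snap)) unlist(m$snap) else NULL
  params <- if (length(m$parameters)) unlist(m$parameters) else character()
  if (length(m$derived)) {
    for (nm in names(m$derived)) {
      rf <- parseRationalExpression(m$derived[[nm]], character(), params, snap)
      stopifnot(qpDegree(rf$den) <= 0)
      params[nm] <- cpp_rat_arith("div", if (qpIsZero(rf$num)) "0" else rf$num@coefs[1],
                                  rf$den@coefs[1])
    }
  }
  mkConstraint <- function(cc) {
    coefs <- vapply(cc$coeffs, function(e) {
      rf <- parseRationalExpression(as.character(e), character(), params, snap)
      cpp_rat_arith("div", if (qpIsZero(rf$num)) "0" else rf$num@coefs[1], rf$den@coefs[1])
    }, character(1))
    conservationConstraint(coefs, rationalize(as.character(cc$total), snap),
                           victim = if (is.null(cc$victim)) NA_character_ else cc$victim)
  }
  constraints <- lapply(m$constraints %||% list(), mkConstraint)
  if (!is.null(m$reactions)) {
    reacts <- lapply(m$reactions, function(r)
      reaction(unlist(r$reactants), unlist(r$products), r$k,
               label = r$label %||% ""))
    nw <- reactionNetwork(unlist(m$variables), reacts, params,
                          fixed = unlist(m$fixed) %||% character(), snap = snap)
    sys <- massActionOdes(nw)
    for (cc in constraints) sys <- eliminateConserved(sys, cc)
  } else if (!is.null(m$odes)) {
    sys <- odeSystem(unlist(m$variables),
                     vapply(m$odes, as.character, character(1)),
                     params, constraints, snap)
  } else stop("model must declare 'reactions' or 'odes'")
  sys@metadata <- list(
    name = m$name %||% basename(path),
    description = m$description %||% "",
    outputs = unlist(m$outputs) %||% character(),
    order = unlist(m$order) %||% NULL,
    scan = if (length(m$scan)) list(parameter = m$scan$parameter,
                                    lo = as.numeric(m$scan$lo),
                                    hi = as.numeric(m$scan$hi)) else NULL
  )
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a packaged fixture model
#'
#' Available fixtures: `wilhelm` (smallest bistable mass-action network),
#' `edelstein` (autocatalytic scheme with a conserved enzyme moiety),
#' `example3` (bistable with an unswitchable output), `example4`
#' (factorizable network with inflow `v`, a scan target), `akt`
#' (insulin/pAKT switch with input `lambda`, a scan target), `mapk`
#' (dual MEK phosphorylation; Michaelis constants and maximal rates derived
#' from the elementary parameters) and `ras` (RAS activation switch with
#' two conserved totals).
#'
#' @param name fixture name, see [listFixtures()]
#' @return a [RationalODESystem]
#' @examples
#' sys <- loadFixture("wilhelm")
#' sys
#' @export
loadFixture <- function(name) {
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "switchscan")
  if (!nzchar(path))
    stop("unknown fixture '", name, "'; available: ",
         paste(listFixtures(), collapse = ", "))
  readModel(path)
}
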