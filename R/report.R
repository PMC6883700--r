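# The analysis procedure: Groebner basis -> triangular solve -> admissibility
# -> Jacobian classification -> bistability verdict -> per-output
# switchability (with reordering/fallback), assembled into a serializable
# report.

#' Analyze a model for bistability and output switchability
#'
#' Runs the four analysis steps: (1) compute the reduced lex Groebner basis
#' of the steady-state system (per factor component when equations
#' factorize); (2) solve the triangular system and keep the nonnegative
#' distinct real solutions, then classify each by the eigenvalues of the
#' Jacobian and decide fixed-point bistability; (3) for each requested
#' output, obtain the univariate basis polynomial (reordering variables as
#' needed) and apply the switchability conditions; (4) fall back to the
#' direct comparison of output values at the two stable states when the
#' univariate route is unavailable.
#'
#' @param x a [RationalODESystem], [ReactionNetwork], fixture name, or path
#'   to a model JSON file
#' @param outputs output variables to test (default: the model's declared
#'   outputs, else all state variables)
#' @param ranking lex ranking (default: the model's declared order, else the
#'   variable order)
#' @param backend Groebner backend ([groebnerBasis()])
#' @param tol tolerance list ([solverTolerances()])
#' @param stabilityTol marginality threshold on eigenvalue real parts
#' @param pairCap S-pair resource guard
#' @return an [AnalysisReport]
#' @examples
#' rep <- analyzeModel("wilhelm")
#' rep
#' @export
analyzeModel <- function(x, outputs = NULL, ranking = NULL,
                         backend = "internal", tol = solverTolerances(),
                         stabilityTol = 1e-9, pairCap = 20000) {
  t0 <- proc.time()[["elapsed"]]
  system <- if (is(x, "RationalODESystem")) x
    else if (is(x, "ReactionNetwork")) massActionOdes(x)
    else if (is.character(x) && file.exists(x)) readModel(x)
    else if (is.character(x)) loadFixture(x)
    else stop("cannot analyze object of class ", class(x)[1])
  meta <- system@metadata
  if (is.null(ranking)) ranking <- meta$order %||% system@variables
  if (is.null(outputs)) {
    outputs <- meta$outputs %||% character()
    if (!length(outputs)) outputs <- system@variables
  }
  sol <- solveSteadyStates(system, ranking, tol, backend = backend, pairCap = pairCap)
  records <- stabilityRecords(sol$states, system, stabilityTol)
  uniVar <- ranking[length(ranking)]
  verdict <- if (nrow(records)) bistabilityVerdict(records, outputVar = uniVar) else
    list(status = "not_bistable", admissibleCount = 0L,
         pattern = character(), countedRows = integer())
  sw <- lapply(outputs, function(ov)
    outputSwitchable(system, records, verdict, ov, solve = sol,
                     tol = tol$distinct, backend = backend, pairCap = pairCap))
  names(sw) <- outputs
  new("AnalysisReport",
      model = meta$name %||% "model",
      system = system,
      basis = sol$basis,
      states = records,
      verdict = verdict,
      switchability = sw,
      scan = list(),
      meta = list(version = as.character(utils::packageVersion("switchscan")),
                  ranking = ranking, backend = backend,
                  tolerances = tol, stabilityTol = stabilityTol,
                  elapsed = proc.time()[["elapsed"]] - t0))
}

setMethod("show", "AnalysisReport", function(object) {
  cat("switchscan analysis of '", object@model, "'\n", sep = "")
  cat("  lex order: ", paste(object@meta$ranking, collapse = " > "),
      "  (univariate in ", object@meta$ranking[length(object@meta$ranking)], ")\n", sep = "")
  st <- object@states
  adm <- st[which(st$admissible), , drop = FALSE]
  vars <- c(object@system@variables, names(object@system@eliminated))
  cat("  admissible steady states:", nrow(adm), "\n")
  if (nrow(adm)) {
    for (i in seq_len(nrow(adm))) {
      cat("    (", paste(sprintf("%s = %.6g", vars, as.numeric(adm[i, vars])),
                         collapse = ", "), ")  [", adm$label[i],
          if (isTRUE(adm$boundary[i])) ", boundary branch" else "", "]\n", sep = "")
    }
  }
  cat("  verdict:", object@verdict$status,
      if (length(object@verdict$pattern))
        paste0("(pattern ", paste(substr(object@verdict$pattern, 1, 1), collapse = "-"), ")"),
      "\n")
  for (ov in names(object@switchability)) {
    s <- object@switchability[[ov]]
    cat("  output ", ov, ": ", s$switchable, " (", s$rule, ")\n", sep = "")
  }
  invisible(object)
})

.poly_to_list <- function(p) {
  list(vars = p@vars, exps = unclass(p@exps), coefs = p@coefs,
       text = formatPoly(p))
}

#' Convert an analysis report to plain lists
#'
#' Lossless plain-data form of an [AnalysisReport], suitable for JSON
#' serialization: basis polynomials as exact coefficient lists per monomial,
#' states with admissibility reason codes, eigenvalues, verdicts and the
#' tolerance context of every numeric value.
#'
#' @param report an [AnalysisReport]
#' @return a nested list
#' @export
reportToList <- function(report) {
  st <- report@states
  vars <- c(report@system@variables, names(report@system@eliminated))
  states <- lapply(seq_len(nrow(st)), function(i) {
    ev <- st$eigenvalues[[i]]
    list(values = as.list(setNames(as.numeric(st[i, vars]), vars)),
         admissible = st$admissible[i],
         reason = st$reason[i],
         component = st$component[i],
         boundary = st$boundary[i],
         label = if (is.na(st$label[i])) NULL else st$label[i],
         eigenvalues = if (is.null(ev)) NULL else
           lapply(ev, function(z) list(re = Re(z), im = Im(z))))
  })
  list(model = report@model,
       variables = report@system@variables,
       eliminated = names(report@system@eliminated),
       ranking = report@meta$ranking,
       basis = lapply(report@basis@polys, .poly_to_list),
       states = states,
       verdict = report@verdict[c("status", "admissibleCount", "pattern")],
       switchability = lapply(report@switchability, function(s)
         s[c("output", "switchable", "rule", "outputValues", "cubic")]),
       scan = report@scan,
       meta = report@meta[c("version", "backend", "tolerances", "stabilityTol")])
}

#' Write / read an analysis report as JSON
#'
#' @param report an [AnalysisReport] (or the list form from [reportToList()])
#' @param path output file
#' @return `writeReport` returns `path` invisibly; `readReport` returns the
#'   report list exactly as written
#' @export
writeReport <- function(report, path) {
  x <- if (is(report, "AnalysisReport")) reportToList(report) else report
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
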