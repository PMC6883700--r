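# One-parameter scans of the admissible-state count and verdicts, with
# bisection bracketing of the saddle-node (limit-point) boundaries of the
# bistable region.  Grid-then-bisection with exact per-point analysis
# replaces numerical continuation: at this problem scale every grid point is
# cheap and no continuation machinery is needed.

.scan_point <- function(system, parameter, value, ranking, tol, pairCap) {
  sys <- withParameter(system, parameter, value)
  sol <- solveSteadyStates(sys, ranking, tol, pairCap = pairCap)
  st <- stabilityRecords(sol$states, sys)
  verdict <- if (nrow(st)) bistabilityVerdict(st) else
    list(status = "not_bistable", admissibleCount = 0L, pattern = character(),
         countedRows = integer())
  list(system = sys, states = st, verdict = verdict, solve = sol)
}

#' Parameter scan for bistability
#'
#' Runs the full exact pipeline (Groebner basis, root isolation, stability
#' classification) at each grid value of one parameter and records the
#' admissible-state count, the verdict, and the output values.
#'
#' @param system a [RationalODESystem] carrying its symbolic definition
#' @param parameter parameter name (e.g. the insulin input `lambda`, or the
#'   inflow rate `v`)
#' @param lo,hi scan window, `lo < hi`
#' @param npoints number of equally spaced grid points
#' @param output variable whose steady-state values are recorded (default:
#'   first declared output, else the last variable)
#' @param ranking lex ranking used per point
#' @param tol tolerance list ([solverTolerances()])
#' @param pairCap resource guard for the Groebner engine
#' @return list of class fields: `parameter`, `grid` (data.frame with
#'   `value`, `admissibleCount`, `status`), `outputs` (list of per-point
#'   output values), `boundaries` (empty until [bracketBoundaries()])
#' @export
scanParameter <- function(system, parameter, lo, hi, npoints = 41,
                          output = NULL, ranking = NULL,
                          tol = solverTolerances(), pairCap = 20000) {
  stopifnot(lo < hi, npoints >= 2)
  if (!length(system@definition))
    stop("system carries no symbolic definition; cannot scan")
  # withParameter errors on a non-occurring parameter
  invisible(withParameter(system, parameter, lo))
  if (is.null(output)) {
    output <- if (length(system@metadata$outputs)) system@metadata$outputs[1]
      else system@variables[length(system@variables)]
  }
  grid <- seq(lo, hi, length.out = npoints)
  counts <- integer(npoints)
  status <- character(npoints)
  outvals <- vector("list", npoints)
  for (i in seq_along(grid)) {
    pt <- .scan_point(system, parameter, grid[i], ranking, tol, pairCap)
    counts[i] <- pt$verdict$admissibleCount
    status[i] <- pt$verdict$status
    outvals[[i]] <- if (length(pt$verdict$countedRows))
      as.numeric(pt$states[pt$verdict$countedRows, output]) else numeric()
  }
  list(parameter = parameter, output = output,
       grid = data.frame(value = grid, admissibleCount = counts, status = status),
       outputs = outvals,
       window = c(lo, hi),
       boundaries = list())
}

#' Bracket the saddle-node boundaries of a scan
#'
#' Bisects every grid interval across which the admissible-state count
#' changes, down to `resolution`.  When the univariate basis polynomial in
#' the scan's output variable is a cubic, the sign of its discriminant (zero
#' exactly at the saddle-node, where two states coalesce) drives the
#' bisection; otherwise the admissible-count change itself does.
#'
#' @param system the scanned [RationalODESystem]
#' @param scan result of [scanParameter()]
#' @param resolution final bracket width (default 1e-3)
#' @param useDiscriminant bisect on the cubic discriminant sign when
#'   available (`TRUE`), or always on the count change (`FALSE`)
#' @param ranking,tol,pairCap as in [scanParameter()]
#' @return the scan with `boundaries` filled: a list of records with
#'   `location` (interval midpoint), `width`, `from`, `to` (the straddling
#'   counts) and `route` (`"discriminant"` or `"count"`)
#' @export
bracketBoundaries <- function(system, scan, resolution = 1e-3,
                              useDiscriminant = TRUE, ranking = NULL,
                              tol = solverTolerances(), pairCap = 20000) {
  grid <- scan$grid
  trans <- which(diff(grid$admissibleCount) != 0)
  if (!length(trans)) {
    scan$boundaries <- list()
    return(scan)
  }
  countAt <- function(v) {
    pt <- .scan_point(system, scan$parameter, v, ranking, tol, pairCap)
    pt$verdict$admissibleCount
  }
  discAt <- function(v) {
    sys <- withParameter(system, scan$parameter, v)
    comps <- factorComponents(sys)
    core <- Filter(function(cp) !cp$boundary, comps)
    polys <- if (length(core)) core[[1]]$polys else steadyStatePolys(sys)
    uni <- univariateIn(polys, scan$output, pairCap = pairCap)
    if (is.null(uni)) return(NA_real_)
    ct <- tryCatch(cubicSwitchTest(uni, var = scan$output),
                   notCubicError = function(e) NULL)
    if (is.null(ct)) return(NA_real_)
    cpp_rat_to_double(ct$D)
  }
  boundaries <- list()
  for (ti in trans) {
    a <- grid$value[ti]
    b <- grid$value[ti + 1]
    ca <- grid$admissibleCount[ti]
    cb <- grid$admissibleCount[ti + 1]
    da <- if (useDiscriminant) discAt(a) else NA_real_
    db <- if (useDiscriminant) discAt(b) else NA_real_
    discRoute <- is.finite(da) && is.finite(db) && sign(da) != sign(db)
    while (b - a > resolution) {
      m <- (a + b) / 2
      if (discRoute) {
        dm <- discAt(m)
        if (!is.finite(dm)) { discRoute <- FALSE; next }
        if (sign(dm) == sign(da)) { a <- m; da <- dm } else { b <- m; db <- dm }
      } else {
        cm <- countAt(m)
        if (cm == ca) a <- m else { b <- m; cb <- cm }
      }
    }
    boundaries[[length(boundaries) + 1]] <-
      list(location = (a + b) / 2, width = b - a, from = ca, to = cb,
           route = if (discRoute) "discriminant" else "count")
  }
  scan$boundaries <- boundaries
  scan
}
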