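# The inverse problem: split a target cubic into generation/depletion rates
# and synthesize a mass-action network realizing it.

#' Generation/depletion decomposition of a normalized cubic
#'
#' `|g1(x)|` measures the imbalance between the rate at which the output
#' species is generated and the rate at which it is depleted:
#' `g1 = (b x^2 + d) - (x^3 + c x)`, so a switchable output needs quadratic
#' plus constant generation and cubic plus linear depletion.  Between
#' consecutive roots the sign of (generation - depletion) alternates
#' (+, -, +), producing the bistable switching response.
#'
#' @param b,c,d coefficients of `-x^3 + b x^2 - c x + d` (rational strings
#'   or numerics)
#' @param var variable name
#' @return list with [QPolynomial] `generation` (`|b| x^2 + |d|`) and
#'   `depletion` (`x^3 + c x`); their difference equals the cubic
#' @examples
#' decomposeRates(8, 12, 0)
#' @export
decomposeRates <- function(b, c, d, var = "x") {
  pstr <- function(v) if (is.numeric(v)) rationalize(format(v, digits = 17)) else cpp_rat_norm(v)
  b <- pstr(b); c <- pstr(c); d <- pstr(d)
  babs <- if (cpp_rat_cmp(b, "0") < 0) cpp_rat_arith("mul", "-1", b) else b
  dabs <- if (cpp_rat_cmp(d, "0") < 0) cpp_rat_arith("mul", "-1", d) else d
  generation <- qpFromUniCoefs(var, c(dabs, "0", babs))
  depletion <- qpFromUniCoefs(var, c("0", c, "0", "1"))
  list(generation = generation, depletion = depletion)
}

#' Synthesize a mass-action network realizing a target cubic
#'
#' Builds the four-reaction template (`S+Y -> 2X`, `2X -> X+Y`,
#' `X+Y -> Y+P`, `X -> P`, with S lumped and P inert) whose reduced
#' x-dynamics, after substituting the steady-state relation
#' `y = (k2/k1) x^2`, is exactly `-x^3 + b x^2 - c x (+ d)`.  The scaling
#' freedom is resolved by fixing `k3 = 1` and `k1 = k2 = b` (so the cubic is
#' reproduced exactly, not only its root set); a strictly positive `d` adds
#' a zeroth-order inflow reaction of rate `d`.  The synthesized network is
#' guaranteed bistable and switchable in `x` whenever the target passes the
#' switchability conditions.
#'
#' @param b,c,d target cubic coefficients; must pass [cubicSwitchTest()]
#'   (three distinct nonnegative roots)
#' @param k1 override for the `k1 = k2` pair (defaults to `b`)
#' @return list with the [ReactionNetwork] (`network`), its mass-action
#'   [RationalODESystem] (`system`), and the target coefficients
#' @examples
#' real <- realizeNetwork(8, 12, 0)
#' basisPolys(groebnerBasis(real$system, ranking = c("y", "x")))[[1]]
#' @export
realizeNetwork <- function(b, c, d = 0, k1 = NULL) {
  pstr <- function(v) if (is.numeric(v)) rationalize(format(v, digits = 17)) else cpp_rat_norm(v)
  b <- pstr(b); c <- pstr(c); d <- pstr(d)
  target <- qpFromUniCoefs("x", c(d, cpp_rat_arith("mul", "-1", c), b, "-1"))
  ct <- cubicSwitchTest(target, var = "x")
  if (!ct$pass) {
    stop("target cubic fails the switchability conditions (",
         paste(names(ct$conditions)[!ct$conditions], collapse = ", "),
         "); no bistable realization is attempted")
  }
  if (is.null(k1)) k1 <- b else k1 <- pstr(k1)
  if (cpp_rat_cmp(k1, "0") <= 0) stop("k1 must be positive")
  # k2 chosen so that k3 * (k2/k1) = 1 with k3 = 1
  k2 <- k1
  # reduced dynamics: 2 k1 (k2/k1) x^2 - k2 x^2 - k3 (k2/k1) x^3 - k4 x + d
  #                 = k2 x^2 - x^3 - c x + d, so k2 must equal b
  if (cpp_rat_cmp(k2, b) != 0) {
    # overriding k1 trades exact coefficients for the same root set only
    warning("k1 != b: the realized reduced dynamics matches the target's ",
            "roots up to scaling, not its coefficients")
  }
  reacts <- list(
    reaction(c(y = 1), c(x = 2), "k1", label = "S+Y->2X (S lumped)"),
    reaction(c(x = 2), c(x = 1, y = 1), "k2", label = "2X->X+Y"),
    reaction(c(x = 1, y = 1), c(y = 1, P = 1), "k3", label = "X+Y->Y+P"),
    reaction(c(x = 1), c(P = 1), "k4", label = "X->P")
  )
  params <- c(k1 = k1, k2 = k2, k3 = "1", k4 = c)
  if (cpp_rat_cmp(d, "0") > 0) {
    reacts <- c(reacts, list(reaction(integer(), c(x = 1), "v", label = "0->X (inflow)")))
    params <- c(params, v = d)
  }
  nw <- reactionNetwork(species = c("x", "y"), reactions = reacts,
                        parameters = params, fixed = "P")
  list(network = nw, system = massActionOdes(nw),
       target = list(b = b, c = c, d = d))
}
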