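---
title: "Detecting biological switches with exact Gröbner-basis analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting biological switches with exact Gröbner-basis analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscan)
```

## The model class and its assumptions

`switchscan` analyzes autonomous ODE models of biochemical networks whose
right-hand sides are polynomial or rational in the state,

$$\dot{x}_i \;=\; \frac{f_i(x)}{d_i(x)}, \qquad x \in \mathbb{R}^n_{\ge 0},$$

with exact rational coefficients. Mass-action kinetics gives $d_i \equiv 1$;
Michaelis–Menten and related saturating rate laws give nontrivial
denominators, which are cleared symbolically so that steady states are the
solutions of the polynomial system $f_i(x) = 0$ with $d_i(x) \neq 0$ checked
afterwards. Conserved moieties (total enzyme, total substrate) enter as
linear constraints $\sum_j c_j x_j = c$; the designated variable is
eliminated by substitution at model construction, and the eliminated species
is reconstructed — and required to be nonnegative — whenever steady states
are reported. This is the standard reduction of a
differential–algebraic system to an ODE on the independent coordinates, and
it generates the same steady-state ideal as keeping the constraint as an
extra polynomial equation.

Two definitions drive the analysis:

* **Fixed-point bistability.** The system has exactly three nonnegative,
  distinct, real steady states, two of them stable and one unstable
  (by the eigenvalues of the Jacobian; the unstable one is typically a
  saddle whose stable manifold separates the two basins).
* **Output switchability.** A designated output variable takes *different*
  values at the two stable states. In one dimension bistability implies
  switchability; in higher dimension it does not — a species can sit at the
  same level on both stable branches while the rest of the state switches.

## Why exact arithmetic

The pipeline's central object, the reduced lexicographic Gröbner basis, is
discontinuous in the coefficients: floating-point Buchberger runs can drop
entire solution branches or report spurious low-degree bases. Two of the
packaged signalling fixtures demonstrate this concretely — with their
parameters taken exactly, the MEK dual-phosphorylation cycle has a
*quartic* univariate basis polynomial (one root of which back-substitutes
to a negative concentration and is filtered out), and the RAS model a
degree-8 one with exactly three admissible extensions. Any floating-point
shortcut that reports a cubic there is silently discarding algebra. All
model coefficients are therefore converted to exact rationals up front
(`rationalize("1.5")` → `3/2`), and every algebraic step — Buchberger,
multivariate division, Sturm sequences — runs over arbitrary-precision
rationals in compiled code. Decimal parameters that a model declares to be
*printed roundings* of exact values are mapped back explicitly through a
versioned snap table (for the inflow network: `0.166 → 1/6`,
`1.667 → 5/3`); snapping is never inferred.

## The Gröbner engine

`groebnerBasis()` implements Buchberger's completion with:

* **Lex convention.** "Univariate in $v$" means $v$ is ranked *last*; the
  elimination ideal of a zero-dimensional system then contains a univariate
  polynomial in $v$. Rankings are explicit everywhere
  (`ranking = c("y", "x")` eliminates `y` first).
* **Fraction-free core.** S-polynomials and normal forms run on
  content-stripped integer polynomials (the classic pseudo-division
  trick), avoiding rational normalization in the hot loop; the final basis
  is monic over $\mathbb{Q}$, inter-reduced, and therefore *unique* for a
  given ranking — which is what makes cross-checking against an external
  CAS an exact equality test rather than a tolerance comparison.
* **Determinism.** Normal pair-selection strategy (smallest lcm total
  degree, then lex-smallest lcm, then input index), plus the product and
  chain criteria. A configurable S-pair cap (default 20 000) fails loudly
  on pathological inputs instead of hanging — lexicographic bases can blow
  up doubly exponentially on adversarial systems.
* **Backends.** `internal` (default), `sympy` (via the command-line
  `python`), or `both`, which runs both and errors on any disagreement.
  The test suite cross-checks every fixture component and a battery of
  random systems in `both` mode.

Real roots of the univariate element are isolated exactly: Yun's
squarefree decomposition, Sturm-sequence counting on dyadic intervals, and
sign bisection down to a relative width of $10^{-13}$, with exact rational
roots recognized by evaluation (so the minimal network's roots come back
as literally `0, 2, 6`, not floats near them). Back-substitution extends
each root through the triangular chain — exactly while the partial
solution is rational, numerically (with Newton polishing against the full
system) once an irrational root enters — trying chain elements in order of
degree because a lower element can degenerate to $0=0$ at special partial
roots, and validating every extension against *all* chain polynomials at
its level.

## Admissibility, stability, and the verdict

A candidate state is admissible when all components (including
reconstructed conserved species) are $\ge -10^{-9}$, all cleared
denominators exceed $10^{-9}$ in magnitude, the full-system residuals are
below $10^{-8}$ (scaled by coefficient size), and it is distinct from
previously accepted states at relative $10^{-8}$. These defaults live in
`solverTolerances()`; the exact-rational chain makes the roots accurate to
machine precision, so the tolerances only guard the genuinely numeric
steps.

Stability is read off the eigenvalues of the Jacobian (quotient rule for
rational right-hand sides, evaluated at the state): all real parts below
$-10^{-9}$ is stable, any above $+10^{-9}$ unstable, anything inside the
band is labelled *marginal* and makes the overall verdict `inconclusive`
rather than guessing — linearization is silent at non-hyperbolic points.
The verdict is `bistable` exactly for three admissible states labelled
stable/unstable/stable; more than three admissible states is reported as
`not_bistable` with the count (multistability beyond three is reported,
not adjudicated).

**Factorizable equations.** When an equation factors as
$x_j \cdot h(x) = 0$ (a species that can be absent), the solver enumerates
the components — each factor's vanishing separately — and analyzes them
independently. States on an extinction boundary are kept in the report,
tagged, but excluded from the bistability count when the interior
component supplies the three states on its own: the boundary branch of the
inflow fixture carries a single positive state and cannot participate in
the switching pair. This mirrors the manual case split one would do by
hand for such networks.

## Switchability routing

For each requested output the analysis follows one of three routes, in
order: the normalized-cubic conditions when the univariate basis
polynomial in that output has degree exactly 3 (with the exact
discriminant sign decided in rational arithmetic); the repeated-root rule
when the univariate polynomial exists but cannot have three distinct
admissible roots; and the direct comparison of output values at the two
stable states otherwise. The direct comparison is the *definition* — the
rules are shortcuts — so the implementation computes it in every case and
the test suite asserts that rule and definition never disagree on the
fixtures.

A deliberate design choice concerns univariate polynomials of degree above
three: exact arithmetic frequently produces them (cleared denominators and
eliminated constraints contribute branches that the admissibility filter
later removes). The cubic conditions are stated for cubics only, so such
outputs route to the direct comparison, and the *monic cubic whose roots
are the three admissible output values* is reported alongside — its
coefficients are the quantities a practitioner would quote for the
switching polynomial of the admissible branch (for the RAS fixture, a
quadratic coefficient of about 0.912).

## Bifurcation scans

`scanParameter()` re-runs the full exact pipeline at each grid value of
one parameter (systems carry their symbolic definition precisely so they
can be rebuilt with modified parameters), and `bracketBoundaries()`
bisects every admissible-count transition to a requested resolution
(default $10^{-3}$). When the univariate polynomial in the scan output is
cubic, the bisection tracks the sign of its discriminant — zero exactly at
the saddle-node, where two states coalesce — and otherwise the count
change itself. Grid-then-bisection was chosen over pseudo-arclength
continuation deliberately: each point is an exact, independent analysis,
cheap at this scale, with no step-size or tangent-prediction machinery,
at the cost of not following unstable branches through folds or detecting
Hopf points (out of scope; no limit-cycle analysis is attempted). The
insulin fixture brackets its bistable window at λ ≈ 0.38–0.65 this way,
with the discriminant and count routes agreeing to the resolution.

## Dynamics and design

`integrateSystem()` is a fixed-step classical Runge–Kutta integrator
(default step $10^{-3} \cdot t_{\text{end}}$) with a denominator guard
that truncates trajectories approaching a pole of a rational rate law;
it exists for attractor checks, not for stiff production integration —
the test suite cross-validates terminal states against `deSolve`'s
adaptive `lsoda`. `univariateSystem(b, c, d)` builds the one-dimensional
surrogate $\dot{x} = -x^3 + bx^2 - cx + d$ whose fixed points are the
cubic's roots; for a bistable system with a switchable output, full and
surrogate trajectories reach the same stable output value (their
transients differ), which `sameAttractorCheck()` verifies. Starts within
$10^{-3}$ of the separatrix are excluded from such assertions — basin
membership is genuinely sensitive there and no claim is made.

`realizeNetwork(b, c, d)` inverts the analysis: given a passing cubic it
emits the four-reaction template (autocatalytic production, conversion,
catalyzed degradation, first-order decay, plus a zeroth-order inflow when
$d > 0$) with rate constants $k_1 = k_2 = b$, $k_3 = 1$, $k_4 = c$, chosen
so the reduced output dynamics reproduces the cubic *exactly*, not merely
its root set. One can show the two-species realization is automatically
bistable whenever the cubic passes (the Jacobian determinant at a steady
state equals $-b \cdot g_1'(x)$ and the trace is negative on the
nonnegative orthant), and the test suite round-trips synthesized networks
back through the Gröbner pipeline.

## What the tests do and do not show

The packaged fixtures are small published models with printed parameters;
the suite reproduces their steady states, verdicts, scan boundaries and
basis polynomials, and property-based batteries check the engine against
independent oracles (sympy bases, `polyroot`, multi-start Newton solving,
the squared-root-gap discriminant identity, brute-force stoichiometry
assembly) on seeded random instances. Passing these says the *algebra* is
right. It does not validate any biological model: rate constants from the
literature carry uncertainty the pipeline treats as exact, stochasticity
and spatial effects are outside the model class, and lex-basis complexity
limits routine use to the small (few-variable, after conservation
elimination) systems for which the method is intended. Degree growth is
the practical ceiling: beyond a handful of variables the S-pair cap will
trip, and model reduction (lumping, conservation elimination) is the
remedy, not a larger cap.

## Numerical fine print

* Decimal-to-rational conversion is literal (`0.166 → 83/500`) unless a
  fixture's snap table says otherwise; the two conventions give visibly
  different bases, which the suite checks.
* Several published decimal tables turn out to be *truncated* rather than
  rounded (the autocatalytic fixture's `1.6388… → 1.63`); comparisons to
  such values truncate accordingly.
* Root refinement reports doubles from intervals of relative width
  $10^{-13}$; multiplicities come from the squarefree decomposition, so a
  double root at a fold is reported as one root of multiplicity two, not
  two nearby roots.
* Ties and degeneracies: marginal eigenvalues → `inconclusive`; repeated
  admissible output values at the stable pair → not switchable; a missing
  univariate element (possible only for non-finite solution sets) raises a
  typed condition (`noUnivariateError` / `notZeroDimensionalError`) that
  `univariateIn()` converts into an "absent" result and the switchability
  router treats as the fallback case.
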