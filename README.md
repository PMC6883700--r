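# switchscan

Exact-arithmetic detection of **fixed-point bistability** and **output
switchability** in polynomial and rational ODE models of biochemical
reaction networks, using reduced lexicographic Gröbner bases.

## The problem

Cellular decision circuits — insulin/AKT signalling, the dual
phosphorylation of MEK in the MAPK cascade, RAS activation — often behave
as switches: the steady-state concentrations sit on one of two stable
branches separated by an unstable saddle. Deciding whether a given
mass-action or Michaelis–Menten model is bistable, and *which* of its
species actually switch between the two stable levels, reduces to exact
questions about a polynomial system:

1. Write the steady-state conditions `f_i(x) = 0` (clearing denominators
   of rational rate laws, eliminating conserved moieties such as total
   kinase via their linear constraints).
2. Compute the reduced Gröbner basis of `⟨f_1, …, f_n⟩` under
   lexicographic order. For a finite solution set the basis is
   triangular: a univariate polynomial `g1` in the lowest-ranked variable,
   plus polynomials introducing the remaining variables one at a time.
3. Isolate the real roots of `g1`, back-substitute through the chain, and
   keep the nonnegative, distinct, real solutions with nonvanishing
   denominators. Exactly three such states — classified
   stable/unstable/stable by the eigenvalues of the Jacobian — means
   fixed-point bistability.
4. An output `x1` is **switchable** when its values at the two *stable*
   states differ. When the univariate basis polynomial in the output is a
   cubic, normalize it to

   `g1(x1) = −x1³ + b·x1² − c·x1 + d`

   Then `b > 0`, `c > 0`, `d ≥ 0` together with a positive discriminant
   `D = −27d² + 18bcd − 4c³ − 4b³d + b²c² > 0` guarantee three distinct
   nonnegative roots, hence a switchable output. With fewer or repeated
   roots the output switches only if the repetition involves the unstable
   state; without a usable univariate polynomial the stable-state values
   are compared directly.

The package also solves the inverse design problem — splitting a target
cubic into generation (`|b|x² + |d|`) and depletion (`x³ + cx`) rates and
synthesizing a four-reaction mass-action network that realizes it exactly
— and brackets the saddle-node boundaries of the bistable parameter region
by an exact scan with bisection.

All algebra runs over exact rationals: printed decimal parameters are
converted to fractions (with explicit "snap" tables for values a model
declares as rounded, e.g. `0.166 → 1/6`), and the Buchberger engine,
multivariate division and Sturm-sequence root isolation use
arbitrary-precision integer arithmetic (compiled C++). `sympy`, reached
through the command-line `python`, is available as an optional
cross-check backend for every basis.

## A worked example

The packaged fixture `example4` is a three-species network with a constant
inflow `v` whose species Y can go extinct (the Y-equation factorizes as
`Y · h(X,Y,Z)`):

```r
library(switchscan)
rep <- analyzeModel("example4")
rep
#> switchscan analysis of 'example4'
#>   lex order: X > Y > Z  (univariate in Z)
#>   admissible steady states: 4
#>     (Z = 6.55927, X = 43.024, Y = 0)  [unstable, boundary branch]
#>     (Z = 2, X = 4, Y = 18)  [stable]
#>     (Z = 3, X = 9, Y = 19)  [unstable]
#>     (Z = 4, X = 16, Y = 18)  [stable]
#>   verdict: bistable (pattern s-u-s)
#>   output Z: yes (cubic-conditions)
#>   output X: yes (cubic-conditions)
#>   output Y: no (repeated-root)
```

The extinction branch carries a single positive state and is excluded from
the bistability count; the interior component has exactly three states,
stable–unstable–stable along Z. The univariate basis polynomial and its
normalized cubic coefficients:

```r
g1 <- extractTriangular(rep@basis)$univariate
formatPoly(g1)
#> [1] "Z^3 - 9*Z^2 + 26*Z - 24"
cubicSwitchTest(g1, var = "Z")[c("b", "c", "d", "D", "pass")]
#> $b  "9"   $c  "26"   $d  "24"   $D  "4"   pass TRUE
```

So Z (roots 2, 3, 4 — all distinct) and X (= Z² at steady state) switch,
while Y takes the value 18 at *both* stable states (only the unstable
state sits at 19): the system is bistable yet not switchable in Y.

Other fixtures: `wilhelm` (the minimal bistable mass-action network),
`edelstein`, `example3` (bistable with unswitchable output), `akt`
(bistable for insulin input λ between 0.38 and 0.65), `mapk`, `ras`. A
thin command-line launcher is installed under `exec/`:

```sh
switchscan analyze akt --out report.json
switchscan scan akt --param lambda --lo 0.3 --hi 0.7
switchscan design --b 8 --c 12 --d 0
switchscan fixtures list
```

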