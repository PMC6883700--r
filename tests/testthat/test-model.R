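wilhelmNetwork <- function() {
  reactionNetwork(
    species = c("x", "y"), fixed = "P",
    reactions = list(
      reaction(c(y = 1), c(x = 2), "k1"),
      reaction(c(x = 2), c(x = 1, y = 1), "k2"),
      reaction(c(x = 1, y = 1), c(y = 1, P = 1), "k3"),
      reaction(c(x = 1), c(P = 1), "k4")),
    parameters = c(k1 = "8", k2 = "1", k3 = "1", k4 = "1.5"))
}

test_that("mass-action assembly reproduces the minimal bistable system", {
  sys <- massActionOdes(wilhelmNetwork())
  vars <- c("x", "y")
  x <- qpVar(vars, "x"); y <- qpVar(vars, "y")
  # dx/dt = 2 k1 y - k2 x^2 - k3 x y - k4 x = 16y - x^2 - xy - 1.5x
  expect_true(qpIsZero(rhsNumerators(sys)[[1]] - (16 * y - x^2 - x * y - "3/2" * x)))
  # dy/dt = k2 x^2 - k1 y
  expect_true(qpIsZero(rhsNumerators(sys)[[2]] - (x^2 - 8 * y)))
  expect_true(all(vapply(rhsDenominators(sys), function(d)
    identical(d@coefs, "1"), logical(1))))
})

test_that("empty network gives all-zero right-hand sides", {
  sys <- massActionOdes(reactionNetwork(c("a", "b"), list()))
  expect_true(all(vapply(rhsNumerators(sys), qpIsZero, logical(1))))
})

test_that("mass-action rhs agrees with brute-force stoichiometry summation", {
  set.seed(21)
  for (rep in 1:5) {
    nw <- randomNetwork(c("A", "B", "C"), nreact = 5)
    sys <- massActionOdes(nw)
    for (trial in 1:10) {
      conc <- setNames(runif(3, 0, 3), c("A", "B", "C"))
      symbolic <- vapply(rhsNumerators(sys), qpEvalNum, numeric(1), point = conc)
      expect_equal(unname(symbolic), unname(bruteForceRhs(nw, conc)), tolerance = 1e-9)
    }
  }
})

test_that("model errors are raised for bad networks", {
  expect_error(reactionNetwork("x", list(reaction(c(q = 1), c(x = 1), "1"))),
               "unknown species")
  nw <- reactionNetwork("x", list(reaction(c(x = 1), integer(), "k1")),
                        parameters = c(k1 = "-2"))
  expect_error(massActionOdes(nw), "nonpositive")
})

test_that("conserved-moiety elimination reproduces the reduced Edelstein system", {
  vars <- c("x1", "x2", "x3")
  sys <- odeSystem(vars,
    c(x1 = "k1*x1 - k2*x1^2 - k3*x1*x2 + k4*x3",
      x2 = "k4*x3 + k5*x3 - k3*x1*x2 - k6*x2"),
    parameters = c(k1 = "8.5", k2 = "1", k3 = "1", k4 = "1", k5 = "1", k6 = "0.2"),
    constraints = list(conservationConstraint(c(x2 = 1, x3 = 1), 30, victim = "x3")))
  expect_identical(variables(sys), c("x1", "x2"))
  v2 <- c("x1", "x2")
  x1 <- qpVar(v2, "x1"); x2 <- qpVar(v2, "x2")
  expect_true(qpIsZero(rhsNumerators(sys)[[1]] -
    ("17/2" * x1 - x1^2 - x1 * x2 - x2 + 30)))
  expect_true(qpIsZero(rhsNumerators(sys)[[2]] -
    (0 - x1 * x2 + 60 - "11/5" * x2)))
  # the eliminated species is reconstructed linearly
  expect_true(qpIsZero(sys@eliminated$x3 - (30 - x2)))
})

test_that("elimination with an absent victim is bookkeeping only", {
  sys <- massActionOdes(wilhelmNetwork())
  cc <- conservationConstraint(c(x = 1, w = 1), 5, victim = "w")
  out <- eliminateConserved(sys, cc)
  expect_identical(variables(out), variables(sys))
  expect_length(constraints(out), 1)
})

test_that("elimination preserves the steady-state set (Table-1-style network)", {
  # synthetic reconstruction of the conserved-moiety network behind the
  # smallest unswitchable-output system: rates chosen so that the reduced
  # system is close to dZ/dt = -Z^3+6Z^2-11Z+6, dY/dt = -Y-Z^2+4Z+6
  vars <- c("Z", "Y", "X")
  sys3 <- odeSystem(vars,
    c(Z = "-k1*X*Z + k2*X - k4*Z^3 + k5*X*Z^2 - k7*Z + k8*X*Z",
      Y = "k1*X*Z + k2*X - k3*Y"),
    parameters = c(k1 = "1", k2 = "1.1623", k3 = "1", k4 = "1",
                   k5 = "0", k7 = "5.098", k8 = "0.0817"),
    constraints = list(conservationConstraint(c(X = 1, Z = 1), "5.1623",
                                              victim = "X")))
  expect_identical(variables(sys3), c("Z", "Y"))
  # numeric multi-start root finding on the reduced system, then check the
  # original differential-algebraic residuals
  sol <- multiStartNewton(steadyStatePolys(sys3), c("Z", "Y"), 0, 12,
                          nstarts = 150, seed = 4)
  expect_gte(nrow(sol), 1)
  for (i in seq_len(nrow(sol))) {
    Z <- sol[i, "Z"]; Y <- sol[i, "Y"]
    X <- 5.1623 - Z
    # original DAE right-hand sides at the extended state
    f1 <- -1 * X * Z + 1.1623 * X - Z^3 + 0 - 5.098 * Z + 0.0817 * X * Z
    f2 <- X * Z + 1.1623 * X - Y
    expect_lt(max(abs(c(f1, f2, X + Z - 5.1623))), 1e-9)
  }
})

test_that("denominator clearing yields coprime numerator/denominator pairs", {
  vars <- c("u", "v")
  sys <- clearDenominators(c(u = "(u^2 - v)/(u + 1) + v", v = "u - v"), vars)
  # round trip: f/d equals the input expression on random points
  set.seed(31)
  for (i in 1:100) {
    pt <- c(u = runif(1, 0, 5), v = runif(1, 0, 5))
    lhs <- qpEvalNum(rhsNumerators(sys)[[1]], pt) / qpEvalNum(rhsDenominators(sys)[[1]], pt)
    expect_equal(lhs, (pt[["u"]]^2 - pt[["v"]]) / (pt[["u"]] + 1) + pt[["v"]],
                 tolerance = 1e-10)
  }
  # polynomial input stays polynomial
  expect_identical(rhsDenominators(sys)[[2]]@coefs, "1")
  # a blatant common factor cancels
  sys2 <- clearDenominators(c(u = "(u^2 + u*v)/(u + v)", v = "0"), vars)
  expect_identical(rhsDenominators(sys2)[[1]]@coefs, "1")
  expect_true(qpIsZero(rhsNumerators(sys2)[[1]] - qpVar(vars, "u")))
  # non-rational constructs are rejected
  expect_error(clearDenominators(c(u = "exp(u)", v = "0"), vars), "unknown identifier")
})

test_that("structural conservation is recognized symbolically", {
  nw <- reactionNetwork(c("A", "B"),
    list(reaction(c(A = 1), c(B = 1), "1"), reaction(c(B = 1), c(A = 1), "2")))
  sys <- massActionOdes(nw)
  expect_true(isStructuralConservation(sys,
    conservationConstraint(c(A = 1, B = 1), 1)))
  # the minimal bistable network does not conserve x + y
  expect_false(isStructuralConservation(massActionOdes(wilhelmNetwork()),
    conservationConstraint(c(x = 1, y = 1), 1)))
})
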