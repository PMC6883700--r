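test_that("fixed-step integration matches closed forms and an adaptive oracle", {
  lin <- odeSystem("x", c(x = "-x"))
  tr <- integrateSystem(lin, c(x = 1), tEnd = 10, step = 0.01)
  expect_equal(tr$terminal[["x"]], exp(-10), tolerance = 1e-8)
  # basin membership agrees with deSolve's adaptive integrator
  sys <- loadFixture("wilhelm")
  st <- solveSteadyStates(sys, c("y", "x"))$states
  starts <- list(c(x = 0.1, y = 0.1), c(x = 5, y = 5))
  expected <- c(1, 3)  # rows of st: (0,0) and (6,4.5)
  deriv <- function(t, state, parms) {
    list(vapply(seq_along(rhsNumerators(sys)), function(i)
      qpEvalNum(rhsNumerators(sys)[[i]], state), numeric(1)))
  }
  for (k in seq_along(starts)) {
    tr <- integrateSystem(sys, starts[[k]], tEnd = 60, step = 0.02, states = st)
    expect_identical(tr$convergedTo, as.integer(expected[k]))
    ode <- deSolve::lsoda(starts[[k]], c(0, 60), deriv, NULL,
                          rtol = 1e-10, atol = 1e-10)
    ref <- ode[nrow(ode), c("x", "y")]
    expect_equal(unname(tr$terminal), unname(unlist(ref)), tolerance = 1e-4)
  }
})

test_that("the unswitchable output settles at the same value from both basins", {
  sys <- loadFixture("example3")
  st <- solveSteadyStates(sys, c("Z", "Y"))$states
  set.seed(43)
  for (i in 1:6) {
    x0 <- c(Z = runif(1, 0, 4), Y = runif(1, 5, 12))
    if (abs(x0[["Z"]] - 2) < 0.2) next  # keep clear of the separatrix
    tr <- integrateSystem(sys, x0, tEnd = 80, step = 0.02, states = st)
    expect_true(tr$converged)
    expect_lt(abs(tr$terminal[["Y"]] - 9), 1e-3)
  }
})

test_that("the 1-D univariate dynamics has the cubic's roots as fixed points", {
  sys1 <- univariateSystem(8, 12, 0)
  sol <- solveSteadyStates(sys1)
  st <- stabilityRecords(sol$states, sys1)
  st <- st[order(st$x), ]
  expect_equal(st$x, c(0, 2, 6), tolerance = 1e-10)
  expect_identical(st$label, c("stable", "unstable", "stable"))
  sys2 <- univariateSystem(6, 11, 6)
  st2 <- stabilityRecords(solveSteadyStates(sys2)$states, sys2)
  st2 <- st2[order(st2$x), ]
  expect_equal(st2$x, c(1, 2, 3), tolerance = 1e-10)
  expect_identical(st2$label, c("stable", "unstable", "stable"))
  # a large constant input with D < 0 leaves a single fixed point
  ct <- cubicSwitchTest(qpFromUniCoefs("x", c("50", "-12", "8", "-1")))
  expect_false(ct$pass)
  sys3 <- univariateSystem(8, 12, 50)
  expect_identical(sum(solveSteadyStates(sys3)$states$admissible), 1L)
})

test_that("full and univariate trajectories reach the same stable output", {
  # autocatalytic two-variable model vs its univariate output dynamics
  sys <- loadFixture("edelstein")
  uni <- univariateIn(steadyStatePolys(sys), "x1")
  ct <- cubicSwitchTest(uni, var = "x1")
  expect_true(ct$pass)
  usys <- univariateSystem(ct$b, ct$c, ct$d, var = "x1")
  expect_true(sameAttractorCheck(sys, usys, "x1", c(x1 = 0.5, x2 = 18),
                                 tEnd = 200, step = 0.02))
  # starting exactly at a stable fixed point is trivially in agreement
  expect_true(sameAttractorCheck(sys, usys, "x1", c(x1 = 1, x2 = 18.75),
                                 tEnd = 50, step = 0.02))
  # random starts on the minimal bistable network, separatrix excluded
  w <- loadFixture("wilhelm")
  uw <- cubicSwitchTest(univariateIn(steadyStatePolys(w), "x"))
  uwsys <- univariateSystem(uw$b, uw$c, uw$d, var = "x")
  set.seed(47)
  checked <- 0
  for (i in 1:8) {
    x0 <- c(x = runif(1, 0, 8), y = runif(1, 0, 6))
    # skip starts whose full-system output lands near the unstable root
    if (abs(x0[["x"]] - 2) < 0.5) next
    agree <- sameAttractorCheck(w, uwsys, "x", x0, tEnd = 120, step = 0.02)
    if (is.na(agree)) next
    # the univariate system partitions basins by the output alone; compare
    # only when both start on the same side of the separatrix surface
    tr <- integrateSystem(w, x0, tEnd = 120, step = 0.02)
    tru <- integrateSystem(uwsys, c(x = x0[["x"]]), tEnd = 120, step = 0.02)
    sameBasin <- sign(tr$terminal[["x"]] - 2) == sign(tru$terminal[["x"]] - 2)
    if (sameBasin) {
      checked <- checked + 1
      expect_true(agree)
    }
  }
  expect_gt(checked, 2)
})

test_that("trajectories truncate when a denominator vanishes", {
  sys <- clearDenominators(c(u = "1/(1 - u)"), "u")
  # u(t) = 1 - sqrt(1 - 2t) blows up at t = 1/2; with a visible guard band
  # the trajectory stops before crossing the pole
  tr <- integrateSystem(sys, c(u = 0), tEnd = 2, step = 0.001, denTol = 1e-2)
  expect_true(tr$truncated)
  expect_lt(max(tr$states[, "u"]), 1)
})
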