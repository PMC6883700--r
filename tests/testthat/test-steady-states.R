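test_that("real-root isolation finds exact roots with multiplicities", {
  p <- qpFromUniCoefs("x", c("0", "12", "-8", "1"))  # x^3 - 8x^2 + 12x
  rr <- realRoots(p)
  expect_equal(rr$value, c(0, 2, 6))
  expect_identical(rr$multiplicity, c(1L, 1L, 1L))
  expect_identical(rr$exact, c("0", "2", "6"))
  # double root
  rr2 <- realRoots(qpFromUniCoefs("x", c("0", "0", "1")))
  expect_equal(rr2$value, 0)
  expect_identical(rr2$multiplicity, 2L)
  # quadratic with the two output values of the unswitchable system
  rr3 <- realRoots(qpFromUniCoefs("Y", c("90", "-19", "1")))
  expect_equal(rr3$value, c(9, 10))
  # irrational roots are refined to near machine precision
  rr4 <- realRoots(qpFromUniCoefs("x", c("-2", "0", "1")))
  expect_equal(rr4$value, c(-sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_error(realRoots(qpFromUniCoefs("x", "0")), "zero polynomial")
})

test_that("root isolation agrees with polyroot on random polynomials", {
  set.seed(29)
  for (i in 1:100) {
    deg <- sample(1:6, 1)
    co <- sample(-9:9, deg + 1, TRUE)
    while (co[deg + 1] == 0) co[deg + 1] <- sample(-9:9, 1)
    rr <- realRoots(as.character(co))
    pr <- polyroot(co)
    ref <- sort(Re(pr)[abs(Im(pr)) < 1e-7 * (1 + abs(Re(pr)))])
    mine <- sort(rep(rr$value, rr$multiplicity))
    expect_length(mine, length(ref))
    if (length(ref)) expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("back-substitution extends univariate roots through the chain", {
  # minimal bistable system
  sys <- loadFixture("wilhelm")
  gb <- groebnerBasis(steadyStatePolys(sys), c("y", "x"))
  states <- backSubstitute(extractTriangular(gb))
  vals <- t(vapply(states, function(s) s$values[c("x", "y")], numeric(2)))
  expect_equal(vals[order(vals[, 1]), ],
               cbind(x = c(0, 2, 6), y = c(0, 0.5, 4.5)), tolerance = 1e-10)
  # chain with a degenerating element: (Y, Z) in {(9,1), (10,2), (9,3)}
  sys3 <- loadFixture("example3")
  gb3 <- groebnerBasis(steadyStatePolys(sys3), c("Z", "Y"))
  st3 <- backSubstitute(extractTriangular(gb3))
  vals3 <- t(vapply(st3, function(s) s$values[c("Y", "Z")], numeric(2)))
  vals3 <- vals3[order(vals3[, 2]), ]
  expect_equal(vals3, cbind(Y = c(9, 10, 9), Z = c(1, 2, 3)), tolerance = 1e-10)
  # trivial chain
  g1 <- groebnerBasis(list(qpVar("x", "x") - 5), "x")
  st1 <- backSubstitute(extractTriangular(g1))
  expect_equal(st1[[1]]$values[["x"]], 5)
})

test_that("admissibility filtering drops negative, duplicate and boundary-violating states", {
  sys <- odeSystem("x", c(x = "x^2 - x - 2"))  # roots -1 and 2
  gb <- groebnerBasis(steadyStatePolys(sys), "x")
  st <- backSubstitute(extractTriangular(gb))
  tab <- admissibleFilter(st, sys)
  expect_identical(tab$admissible, c(FALSE, TRUE))
  expect_identical(tab$reason[1], "negative-component")
  expect_equal(tab$x[tab$admissible], 2)
})

test_that("factorizable networks keep the interior triple and tag the boundary", {
  sys <- loadFixture("example4")
  sol <- solveSteadyStates(sys, c("X", "Y", "Z"))
  st <- sol$states
  adm <- st[st$admissible, ]
  interior <- adm[!adm$boundary, ]
  interior <- interior[order(interior$Z), ]
  expect_equal(as.matrix(interior[, c("Z", "X", "Y")]),
               matrix(c(2, 4, 18, 3, 9, 19, 4, 16, 18), 3, byrow = TRUE,
                      dimnames = list(NULL, c("Z", "X", "Y"))), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the extinction branch has a single positive solution, flagged as boundary
  bd <- adm[adm$boundary, ]
  expect_identical(nrow(bd), 1L)
  expect_equal(bd$Y, 0, tolerance = 1e-12)
  expect_equal(bd$Z, 6.559266, tolerance = 1e-5)
})

test_that("the MAPK triple matches the independently computed admissible roots", {
  # expected values frozen from an independent CAS computation (sympy
  # nroots of the exact lex basis, with the negative-z branch removed)
  sys <- loadFixture("mapk")
  sol <- solveSteadyStates(sys, c("x", "y"))
  adm <- sol$states[sol$states$admissible, ]
  expect_identical(nrow(adm), 3L)
  expect_equal(sort(adm$y), c(0.00340140154068908, 0.141610142098423,
                              0.934875026433147), tolerance = 1e-9)
  expect_equal(sort(adm$x, decreasing = TRUE),
               c(0.966989395878251, 0.696274443682603, 0.0115279851747089),
               tolerance = 1e-8)
  # eliminated z is reconstructed and nonnegative
  expect_true(all(adm$z > 0))
  expect_equal(adm$x + adm$y + adm$z, rep(1, 3), tolerance = 1e-9)
})

test_that("admissible states satisfy the original steady-state residuals", {
  for (f in c("wilhelm", "example3", "akt", "mapk")) {
    sys <- loadFixture(f)
    sol <- solveSteadyStates(sys, sys@metadata$order)
    adm <- sol$states[sol$states$admissible, , drop = FALSE]
    for (i in seq_len(nrow(adm))) {
      pt <- setNames(as.numeric(adm[i, variables(sys)]), variables(sys))
      for (p in steadyStatePolys(sys)) {
        scale <- 1 + max(abs(ratToNumeric(p@coefs)))
        expect_lt(abs(qpEvalNum(p, pt)), 1e-8 * scale)
      }
    }
  }
})

test_that("the admissible set matches dense multi-start root finding", {
  for (f in c("wilhelm", "example3", "akt")) {
    sys <- loadFixture(f)
    sol <- solveSteadyStates(sys, sys@metadata$order)
    adm <- sol$states[sol$states$admissible, , drop = FALSE]
    vars <- variables(sys)
    ref <- multiStartNewton(steadyStatePolys(sys), vars, 0, 8, nstarts = 300, seed = 6)
    mine <- as.matrix(adm[, vars, drop = FALSE])
    mine <- mine[order(mine[, 1]), , drop = FALSE]
    expect_identical(nrow(mine), nrow(ref))
    expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
  }
})

test_that("the admissible set is invariant to the lex ranking", {
  for (f in c("wilhelm", "example3")) {
    sys <- loadFixture(f)
    vars <- variables(sys)
    ref <- NULL
    for (perm in list(vars, rev(vars))) {
      sol <- solveSteadyStates(sys, perm)
      adm <- sol$states[sol$states$admissible, vars, drop = FALSE]
      adm <- as.matrix(adm[order(adm[, 1]), , drop = FALSE])
      if (is.null(ref)) ref <- adm else expect_equal(unname(adm), unname(ref),
                                                     tolerance = 1e-8)
    }
  }
})
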