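test_that("symbolic Jacobians match finite differences and known forms", {
  sys <- loadFixture("wilhelm")
  J <- jacobianSystem(sys)
  # dx/dt = 16y - x^2 - xy - 1.5x, dy/dt = x^2 - 8y:
  # J = [[-2x - y - 1.5, 16 - x], [2x, -8]]
  pt <- c(x = 1.7, y = 0.4)
  m <- evalJacobian(J, pt)
  expect_equal(m, rbind(c(-2 * 1.7 - 0.4 - 1.5, 16 - 1.7), c(2 * 1.7, -8)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # finite-difference cross-check on a rational-rhs model
  akt <- loadFixture("akt")
  Ja <- jacobianSystem(akt)
  p0 <- c(x1 = 0.3, x2 = 0.9)
  h <- 1e-7
  fd <- matrix(0, 2, 2)
  fval <- function(p) vapply(1:2, function(i)
    qpEvalNum(rhsNumerators(akt)[[i]], p) / qpEvalNum(rhsDenominators(akt)[[i]], p),
    numeric(1))
  for (j in 1:2) {
    dp <- p0; dp[j] <- dp[j] + h
    fd[, j] <- (fval(dp) - fval(p0)) / h
  }
  expect_equal(evalJacobian(Ja, p0), fd, tolerance = 1e-5, ignore_attr = TRUE)
  # a linear system's Jacobian is its matrix
  lin <- odeSystem(c("u", "v"), c(u = "-2*u + v", v = "u - 3*v"))
  expect_equal(evalJacobian(jacobianSystem(lin), c(u = 5, v = -2)),
               rbind(c(-2, 1), c(1, -3)), ignore_attr = TRUE)
})

test_that("eigenvalue classification labels saddle and node correctly", {
  sys <- loadFixture("wilhelm")
  J <- jacobianSystem(sys)
  # (2, 0.5): saddle (det J = -8 < 0)
  saddle <- classifySteadyState(c(x = 2, y = 0.5), J)
  expect_identical(saddle$label, "unstable")
  expect_lt(prod(Re(saddle$eigenvalues)), 0)
  # (0, 0): stable node with eigenvalues -1.5 and -8 (triangular Jacobian)
  node <- classifySteadyState(c(x = 0, y = 0), J)
  expect_identical(node$label, "stable")
  expect_equal(sort(Re(node$eigenvalues)), c(-8, -1.5), tolerance = 1e-12)
  # 1-D dx/dt = -x at 0
  one <- odeSystem("x", c(x = "-x"))
  expect_identical(classifySteadyState(c(x = 0), jacobianSystem(one))$label,
                   "stable")
  # marginal case: dx/dt = -x^3 at 0 (zero eigenvalue)
  flat <- odeSystem("x", c(x = "-x^3"))
  expect_identical(classifySteadyState(c(x = 0), jacobianSystem(flat))$label,
                   "marginal")
})

test_that("eigenvalues at exact rational states are accurate", {
  sys <- loadFixture("example3")
  sol <- solveSteadyStates(sys, c("Z", "Y"))
  st <- stabilityRecords(sol$states, sys)
  # Jacobian [[ -3Z^2 + 12Z - 11, 0], [-2Z + 4, -1]]: eigenvalues are the
  # diagonal entries (triangular), computable in closed form
  for (i in seq_len(nrow(st))) {
    Z <- st$Z[i]
    expect_equal(sort(Re(st$eigenvalues[[i]])),
                 sort(c(-3 * Z^2 + 12 * Z - 11, -1)), tolerance = 1e-9)
  }
  labs <- st$label[order(st$Z)]
  expect_identical(labs, c("stable", "unstable", "stable"))
})

test_that("the bistability verdict follows the three-state rule", {
  rep1 <- analyzeModel("wilhelm")
  expect_identical(rep1@verdict$status, "bistable")
  expect_identical(rep1@verdict$pattern, c("stable", "unstable", "stable"))
  # single steady state cannot be bistable
  one <- odeSystem("x", c(x = "1 - x"))
  sol <- solveSteadyStates(one)
  st <- stabilityRecords(sol$states, one)
  expect_identical(bistabilityVerdict(st)$status, "not_bistable")
  # example3: (10, 2) is the unstable state
  rep3 <- analyzeModel("example3")
  expect_identical(rep3@verdict$status, "bistable")
  unst <- rep3@states[which(rep3@states$label == "unstable"), ]
  expect_equal(c(unst$Y, unst$Z), c(10, 2), tolerance = 1e-10)
  # marginal labels make the verdict inconclusive: pitchfork normal form
  # dx/dt = x^2 (1 - x) has states 0 (double, marginal) and 1
  pf <- odeSystem("x", c(x = "x^2 - x^3"))
  solp <- solveSteadyStates(pf)
  stp <- stabilityRecords(solp$states, pf)
  expect_true("marginal" %in% stp$label)
  # more than three admissible states: reported, not adjudicated
  many <- odeSystem("x", c(x = "-(x-1)*(x-2)*(x-3)*(x-4)*(x-5)"))
  solm <- solveSteadyStates(many)
  stm <- stabilityRecords(solm$states, many)
  vm <- bistabilityVerdict(stm)
  expect_identical(vm$status, "not_bistable")
  expect_identical(vm$admissibleCount, 5L)
})

test_that("the verdict is invariant to the lex-order choice", {
  for (f in c("wilhelm", "example3", "akt")) {
    sys <- loadFixture(f)
    vars <- variables(sys)
    statuses <- vapply(list(vars, rev(vars)), function(perm) {
      sol <- solveSteadyStates(sys, perm)
      st <- stabilityRecords(sol$states, sys)
      bistabilityVerdict(st)$status
    }, character(1))
    expect_identical(statuses[1], statuses[2])
    expect_identical(statuses[1], "bistable")
  }
})

test_that("trajectories perturbed from stable states return to them", {
  sys <- loadFixture("wilhelm")
  sol <- solveSteadyStates(sys, c("y", "x"))
  st <- stabilityRecords(sol$states, sys)
  stable <- st[which(st$label == "stable"), ]
  for (i in seq_len(nrow(stable))) {
    x0 <- pmax(setNames(as.numeric(stable[i, c("x", "y")]), c("x", "y")) +
                 c(0.05, -0.03), 0)
    tr <- integrateSystem(sys, x0, tEnd = 60, step = 0.02, states = st)
    expect_true(tr$converged)
    expect_lt(max(abs(tr$terminal - as.numeric(stable[i, c("x", "y")]))), 1e-4)
  }
})
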