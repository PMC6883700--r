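wilhelmPolys <- function() {
  vars <- c("x", "y")
  x <- qpVar(vars, "x"); y <- qpVar(vars, "y")
  list(f1 = 16 * y - x^2 - x * y - "3/2" * x, f2 = x^2 - 8 * y)
}

test_that("the minimal bistable system's basis matches the known triangular form", {
  F <- wilhelmPolys()
  gb <- groebnerBasis(F, ranking = c("y", "x"))  # univariate in x
  vars <- c("x", "y")
  x <- qpVar(vars, "x"); y <- qpVar(vars, "y")
  # monic scaling of 12x - 8x^2 + x^3 and y - x^2/8
  expect_true(.basis_equals(basisPolys(gb), list(x^3 - 8 * x^2 + 12 * x,
                                                 y - "1/8" * x^2)))
  # inputs lie in the ideal: both reduce to zero modulo the basis
  for (f in F)
    expect_true(qpIsZero(polyReduce(f, basisPolys(gb), ranking = c("y", "x"))))
})

test_that("linear systems reduce to their row-echelon solution", {
  vars <- c("x", "y")
  x <- qpVar(vars, "x"); y <- qpVar(vars, "y")
  gb <- groebnerBasis(list(x + y - 3, x - y - 1), ranking = c("x", "y"))
  expect_true(.basis_equals(basisPolys(gb), list(x - 2, y - 1)))
  # random linear systems: basis equals x_i - solution_i (monic rref)
  set.seed(13)
  for (rep in 1:10) {
    A <- matrix(sample(-5:5, 4), 2)
    if (abs(det(A)) < 1e-9) next
    bvec <- sample(-5:5, 2)
    sol <- solve(A, bvec)
    F <- lapply(1:2, function(i)
      qpConst(vars, A[i, 1]) * x + qpConst(vars, A[i, 2]) * y - bvec[i])
    gb <- groebnerBasis(F, ranking = c("x", "y"))
    vals <- lapply(basisPolys(gb), function(p) p)
    expect_length(vals, 2)
    # solutions agree
    expect_equal(sort(vapply(vals, function(p) {
      rr <- realRoots(p, var = qpVarsUsed(p))
      rr$value[1]
    }, numeric(1))), sort(unname(sol)), tolerance = 1e-9)
  }
})

test_that("the reduced basis is deterministic and idempotent", {
  F <- wilhelmPolys()
  g1 <- groebnerBasis(F, ranking = c("y", "x"))
  g2 <- groebnerBasis(rev(F), ranking = c("y", "x"))
  expect_true(.basis_equals(basisPolys(g1), basisPolys(g2)))
  # recomputing from the basis returns the basis (it is reduced and unique)
  g3 <- groebnerBasis(basisPolys(g1), ranking = c("y", "x"))
  expect_true(.basis_equals(basisPolys(g1), basisPolys(g3)))
})

test_that("internal bases agree with the external CAS oracle", {
  # all fixtures
  for (f in listFixtures()) {
    sys <- loadFixture(f)
    ranking <- sys@metadata$order %||% variables(sys)
    comps <- factorComponents(sys)
    for (comp in comps) {
      gb <- groebnerBasis(comp$polys, ranking, backend = "both")
      expect_s4_class(gb, "GroebnerBasisResult")
    }
  }
  # 50 random sparse systems
  set.seed(17)
  for (i in 1:50) {
    F <- randomSystem()
    F <- Filter(Negate(qpIsZero), F)
    if (!length(F)) next
    expect_s4_class(groebnerBasis(F, backend = "both", pairCap = 10000),
                    "GroebnerBasisResult")
  }
})

test_that("every input reduces to zero modulo the basis on random systems", {
  set.seed(19)
  for (i in 1:25) {
    F <- Filter(Negate(qpIsZero), randomSystem())
    if (!length(F)) next
    vars <- variables(F[[1]])
    gb <- groebnerBasis(F, pairCap = 10000)
    for (f in F)
      expect_true(qpIsZero(polyReduce(f, basisPolys(gb), ranking = lexRanking(gb))))
  }
})

test_that("the S-pair resource guard fails loudly", {
  vars <- c("x", "y", "z")
  set.seed(23)
  F <- lapply(1:3, function(i) randomPoly(vars, maxdeg = 4, nterms = 5))
  expect_error(groebnerBasis(F, pairCap = 2), "S-pair limit")
})

test_that("triangular extraction identifies the univariate element and chain", {
  # the two-polynomial unswitchable-output system: three basis elements for
  # two unknowns, all retained
  vars <- c("Z", "Y")
  Z <- qpVar(vars, "Z"); Y <- qpVar(vars, "Y")
  F <- list(0 - Z^3 + 6 * Z^2 - 11 * Z + 6, 0 - Y - Z^2 + 4 * Z + 6)
  gb <- groebnerBasis(F, ranking = c("Z", "Y"))
  tri <- extractTriangular(gb)
  expect_true(qpIsZero(tri$univariate - (Y^2 - 19 * Y + 90)))
  expect_length(tri$chain, 3)
  expect_identical(formatPoly(tri$chain[[1]]), formatPoly(tri$univariate))
  # single polynomial chain
  g1 <- groebnerBasis(list(qpVar("x", "x") - 5), ranking = "x")
  expect_length(extractTriangular(g1)$chain, 1)
})

test_that("degenerate ideals raise typed conditions", {
  vars <- c("x", "y")
  x <- qpVar(vars, "x"); y <- qpVar(vars, "y")
  # x(x-1) = 0 leaves y unconstrained: no univariate in y
  gb <- groebnerBasis(list(x^2 - x), ranking = c("x", "y"))
  expect_error(extractTriangular(gb), class = "noUnivariateError")
  expect_null(univariateIn(list(x^2 - x), "y"))
  # y^2 = 1 with x free: a univariate exists but the set is infinite
  gb2 <- groebnerBasis(list(y^2 - 1), ranking = c("x", "y"))
  expect_error(extractTriangular(gb2), class = "notZeroDimensionalError")
})

test_that("reordering the ranking moves the univariate element", {
  F <- wilhelmPolys()
  vars <- c("x", "y")
  y <- qpVar(vars, "y")
  # univariate in y: monic scaling of -2.25y + 5y^2 - y^3
  uy <- univariateIn(F, "y")
  expect_true(qpIsZero(uy - (y^3 - 5 * y^2 + "9/4" * y)))
  # trivial case
  expect_true(qpIsZero(univariateIn(list(qpVar("x", "x") - 1), "x") -
                         (qpVar("x", "x") - 1)))
  # factorizable three-species network, interior component, univariate in Z
  sys <- loadFixture("example4")
  interior <- Filter(function(cp) !cp$boundary, factorComponents(sys))[[1]]
  uz <- univariateIn(interior$polys, "Z")
  Zv <- qpVar(variables(sys), "Z")
  expect_true(qpIsZero(uz - (Zv^3 - 9 * Zv^2 + 26 * Zv - 24)))
})

test_that("basis solutions coincide with the input system's solutions", {
  # numeric multi-start solutions of F and of its basis agree on fixtures
  for (f in c("wilhelm", "example3")) {
    sys <- loadFixture(f)
    ranking <- sys@metadata$order
    F <- steadyStatePolys(sys)
    gb <- groebnerBasis(F, ranking)
    solF <- multiStartNewton(F, variables(sys), 0, 12, nstarts = 250, seed = 2)
    solG <- multiStartNewton(basisPolys(gb), variables(sys), 0, 12,
                             nstarts = 250, seed = 3)
    expect_identical(nrow(solF), nrow(solG))
    expect_equal(solF, solG[, colnames(solF), drop = FALSE], tolerance = 1e-7)
  }
})
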