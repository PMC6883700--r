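test_that("lexicographic monomial comparison follows the ranking", {
  # x^2 y vs x y^3 under x > y: first exponent decides
  expect_identical(lexCompare(c(x = 2, y = 1), c(x = 1, y = 3)), 1L)
  m <- c(x = 3, y = 1)
  expect_identical(lexCompare(m, m), 0L)
  # reversing the ranking flips the comparison here
  expect_identical(lexCompare(c(x = 2, y = 1), c(x = 1, y = 3), order = c("y", "x")), -1L)
  expect_error(lexCompare(c(1, 2), c(1, 2, 3)), "length")
})

test_that("lex order is antisymmetric and transitive on random monomials", {
  set.seed(3)
  ms <- replicate(60, sample(0:5, 3, TRUE), simplify = FALSE)
  for (k in 1:200) {
    i <- sample(60, 3, TRUE)
    a <- ms[[i[1]]]; b <- ms[[i[2]]]; c <- ms[[i[3]]]
    expect_identical(lexCompare(a, b), -lexCompare(b, a))
    if (lexCompare(a, b) <= 0 && lexCompare(b, c) <= 0)
      expect_lte(lexCompare(a, c), 0)
  }
})

test_that("polynomial arithmetic is exact and canonical", {
  vars <- c("x", "y")
  x <- qpVar(vars, "x"); y <- qpVar(vars, "y")
  p <- 16 * y - x^2 - x * y - "3/2" * x
  expect_identical(formatPoly(p), "- x^2 - x*y - 3/2*x + 16*y")
  expect_true(qpIsZero(p - p))
  expect_identical(qpDegree((x + y)^3), 3L)
  # distributivity on random polynomials
  set.seed(5)
  for (i in 1:20) {
    a <- randomPoly(vars); b <- randomPoly(vars); c <- randomPoly(vars)
    expect_true(qpIsZero(a * (b + c) - (a * b + a * c)))
  }
})

test_that("substitution and differentiation agree with numeric evaluation", {
  vars <- c("x", "y")
  p <- parsePolynomial("3*x^2*y - y^2 + 1/2", vars)
  pt <- c(x = 0.7, y = -1.3)
  expect_equal(qpEvalNum(p, pt), 3 * 0.7^2 * (-1.3) - 1.69 + 0.5, tolerance = 1e-12)
  # d/dx by forward difference
  h <- 1e-7
  dx <- qpDeriv(p, "x")
  expect_equal(qpEvalNum(dx, pt),
               (qpEvalNum(p, pt + c(h, 0)) - qpEvalNum(p, pt)) / h, tolerance = 1e-5)
  # exact substitution
  sub <- qpSubstRat(p, "x", "1/2")
  expect_identical(qpUniCoefs(sub, "y"), c("1/2", "3/4", "-1"))
})

test_that("multivariate division leaves a fully reduced remainder", {
  vars <- c("x", "y")
  x <- qpVar(vars, "x"); y <- qpVar(vars, "y")
  p <- x^2 * y + x * y^2 + y^2
  expect_true(qpIsZero(polyReduce(p, list(p))))
  # member of a generating set reduces to zero
  f1 <- 16 * y - x^2 - x * y - "3/2" * x
  f2 <- x^2 - 8 * y
  expect_true(qpIsZero(polyReduce(f2, list(f2, f1))))
  # self-consistency on random instances: (p - remainder) reduces to zero
  set.seed(7)
  for (i in 1:60) {
    pp <- randomPoly(vars, maxdeg = 3, nterms = 4)
    basis <- list(randomPoly(vars), randomPoly(vars))
    basis <- Filter(Negate(qpIsZero), basis)
    if (!length(basis)) next
    r <- polyReduce(pp, basis)
    expect_true(qpIsZero(polyReduce(pp - r, basis)))
    # no remainder term divisible by a basis leading term
    if (!qpIsZero(r)) {
      for (g in basis) {
        lt <- leadingTerm(g)$exps
        divisible <- apply(r@exps, 1, function(e) all(e >= lt))
        expect_false(any(divisible))
      }
    }
  }
})

test_that("S-polynomials cancel leading terms", {
  vars <- c("x", "y")
  x <- qpVar(vars, "x"); y <- qpVar(vars, "y")
  expect_true(qpIsZero(sPolynomial(x^2 - y, x^2 - y)))
  # coprime leading terms: S-polynomial reduces to zero (Buchberger's
  # first criterion)
  s <- sPolynomial(x - 1, y - 1)
  expect_true(qpIsZero(polyReduce(s, list(x - 1, y - 1))))
  # leading monomial of S(p, q) is strictly below lcm(lt(p), lt(q))
  set.seed(9)
  for (i in 1:50) {
    p <- randomPoly(vars, maxdeg = 3, nterms = 3)
    q <- randomPoly(vars, maxdeg = 3, nterms = 3)
    if (qpIsZero(p) || qpIsZero(q)) next
    s <- sPolynomial(p, q)
    if (qpIsZero(s)) next
    l <- pmax(leadingTerm(p)$exps, leadingTerm(q)$exps)
    expect_identical(lexCompare(leadingTerm(s)$exps, l), -1L)
  }
})

test_that("exact polynomial division detects divisibility", {
  vars <- c("x", "y")
  x <- qpVar(vars, "x"); y <- qpVar(vars, "y")
  p <- (x + y) * (x - 2 * y)
  expect_true(qpIsZero(polyExactDivide(p, x + y) - (x - 2 * y)))
  expect_null(polyExactDivide(p + 1, x + y))
})
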