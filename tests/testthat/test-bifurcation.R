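test_that("a monostable system scans flat with no boundaries", {
  sys <- odeSystem("x", c(x = "lam - x"), parameters = c(lam = "0.5"))
  sc <- scanParameter(sys, "lam", 0, 1, npoints = 6)
  expect_true(all(sc$grid$admissibleCount == 1))
  sc <- bracketBoundaries(sys, sc)
  expect_length(sc$boundaries, 0)
  expect_error(scanParameter(sys, "mu", 0, 1), "does not occur")
})

test_that("the cubic normal form's saddle-node is bracketed at its closed form", {
  # dx/dt = -x^3 + x + lam: saddle-nodes at lam = +-2/(3*sqrt(3)), where the
  # discriminant of the univariate cubic vanishes; the admissible
  # (nonnegative-state) count changes at the negative fold, where the
  # coalescing pair sits at x = +1/sqrt(3)
  sys <- odeSystem("x", c(x = "-x^3 + x + lam"), parameters = c(lam = "0.1"))
  fold <- 2 / (3 * sqrt(3))
  sc <- scanParameter(sys, "lam", -0.5, -0.2, npoints = 16)
  expect_identical(sort(unique(sc$grid$admissibleCount)), c(0L, 2L))
  sc <- bracketBoundaries(sys, sc, resolution = 1e-4)
  expect_length(sc$boundaries, 1)
  expect_equal(sc$boundaries[[1]]$location, -fold, tolerance = 1e-3)
  # the positive fold shows up as a sign change of the cubic discriminant
  Dat <- function(lam) {
    ct <- cubicSwitchTest(qpFromUniCoefs("x", c(rationalize(format(lam, digits = 15)),
                                                "1", "0", "-1")))
    ratToNumeric(ct$D)
  }
  expect_gt(Dat(fold - 1e-3), 0)
  expect_lt(Dat(fold + 1e-3), 0)
})

test_that("the insulin scan brackets the bistable window at 0.38 and 0.65", {
  sys <- loadFixture("akt")
  sc <- scanParameter(sys, "lambda", 0.30, 0.70, npoints = 41,
                      ranking = c("x2", "x1"))
  counts <- sc$grid$admissibleCount
  expect_identical(sort(unique(counts)), c(1L, 3L))
  # 1 ... 3 ... 1 pattern along the grid
  expect_identical(rle(counts)$values, c(1L, 3L, 1L))
  sc <- bracketBoundaries(sys, sc, resolution = 1e-3, ranking = c("x2", "x1"))
  locs <- sort(vapply(sc$boundaries, `[[`, numeric(1), "location"))
  expect_length(locs, 2)
  expect_equal(round(locs, 2), c(0.38, 0.65))
  # inside the bracketed window every grid point is bistable, outside none
  inside <- sc$grid$value > locs[1] + 1e-3 & sc$grid$value < locs[2] - 1e-3
  expect_true(all(sc$grid$status[inside] == "bistable"))
  expect_true(all(sc$grid$status[!inside & (sc$grid$value < locs[1] - 1e-3 |
                                            sc$grid$value > locs[2] + 1e-3)] !=
                    "bistable"))
})

test_that("the inflow scan of the factorizable network recovers the repeated output", {
  sys <- loadFixture("example4")
  sc <- scanParameter(sys, "v", 23, 25, npoints = 3, output = "Y",
                      ranking = c("X", "Y", "Z"))
  i24 <- which(abs(sc$grid$value - 24) < 1e-9)
  expect_identical(sc$grid$admissibleCount[i24], 3L)
  expect_equal(sort(sc$outputs[[i24]]), c(18, 18, 19), tolerance = 1e-9)
})
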