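test_that("the cubic discriminant matches the squared root-gap oracle", {
  # roots {0, 2, 6}: (b,c,d) = (8, 12, 0)
  expect_identical(cubicDiscriminant("8", "12", "0"), "2304")
  expect_equal(rootGapDiscriminant(c(0, 2, 6)), 2304)
  expect_identical(cubicDiscriminant("0", "0", "0"), "0")
  # roots {1, 2, 3}: (b,c,d) = (6, 11, 6)
  expect_identical(cubicDiscriminant("6", "11", "6"), "4")
  expect_equal(rootGapDiscriminant(c(1, 2, 3)), 4)
  # numeric route agrees with the exact route on random coefficients
  set.seed(37)
  for (i in 1:25) {
    r <- sort(runif(3, 0, 5))
    b <- sum(r); c <- r[1] * r[2] + r[1] * r[3] + r[2] * r[3]; d <- prod(r)
    expect_equal(cubicDiscriminant(b, c, d), rootGapDiscriminant(r),
                 tolerance = 1e-6)
  }
})

test_that("the normalized-cubic conditions decide switchability", {
  # 8x^2 - x^3 - 12x normalizes to (b,c,d) = (8,12,0), D = 2304 > 0
  g1 <- qpFromUniCoefs("x", c("0", "-12", "8", "-1"))
  ct <- cubicSwitchTest(g1)
  expect_identical(ct[c("b", "c", "d", "D")],
                   list(b = "8", c = "12", d = "0", D = "2304"))
  expect_true(ct$pass)
  # scaling invariance: monic form of the same polynomial passes identically
  ct2 <- cubicSwitchTest(qpFromUniCoefs("x", c("0", "12", "-8", "1")))
  expect_identical(ct[c("b", "c", "d")], ct2[c("b", "c", "d")])
  # triple root: -(x-1)^3 has D = 0 and fails
  ct3 <- cubicSwitchTest(qpFromUniCoefs("x", c("1", "-3", "3", "-1")))
  expect_identical(ct3$D, "0")
  expect_false(ct3$pass)
  # degree != 3 routes to the fallback
  expect_error(cubicSwitchTest(qpFromUniCoefs("x", c("1", "1"))),
               class = "notCubicError")
})

test_that("passing cubics have three distinct nonnegative roots and (+,-,+) sign pattern", {
  set.seed(41)
  nPass <- 0
  for (i in 1:1000) {
    b <- rationalize(sprintf("%d/%d", sample(1:200, 1), sample(1:20, 1)))
    c <- rationalize(sprintf("%d/%d", sample(1:200, 1), sample(1:20, 1)))
    d <- rationalize(sprintf("%d/%d", sample(0:100, 1), sample(1:20, 1)))
    D <- cubicDiscriminant(b, c, d)
    p <- qpFromUniCoefs("x", c(d, paste0("-", c), b, "-1"))
    rr <- realRoots(p)
    three <- nrow(rr) == 3 && all(rr$multiplicity == 1)
    # D > 0 iff three distinct real roots (root-isolation oracle)
    expect_identical(ratCmp(D, "0") > 0, three)
    if (three) {
      nPass <- nPass + 1
      # Descartes: with b,c > 0, d >= 0 all roots are nonnegative
      expect_true(all(rr$value >= -1e-12))
      # generation - depletion alternates (+, -, +) between consecutive roots
      mids <- (rr$value[-3] + rr$value[-1]) / 2
      lo <- rr$value[1] / 2
      hi <- rr$value[3] + 1
      signs <- sign(vapply(c(lo, mids, hi), function(xx) qpEvalNum(p, c(x = xx)),
                           numeric(1)))
      if (rr$value[1] > 1e-9) expect_identical(signs, c(1, -1, 1, -1))
      else expect_identical(signs[2:4], c(-1, 1, -1))
    }
  }
  expect_gt(nPass, 50)  # the sampler hits genuinely passing cubics
})

test_that("the repeated-root rule follows the stable-pair comparison", {
  # repeated value 9 on both stable states, unstable at 10: not switchable
  expect_false(repeatedRootRule(c(9, 9), 10)$switchable)
  # repetition involving the unstable state with distinct stable values
  expect_true(repeatedRootRule(c(1, 3), 3)$switchable)
})

test_that("per-output verdicts reproduce the worked examples", {
  # two-variable system, both outputs switchable via cubic conditions
  rep1 <- analyzeModel("wilhelm")
  expect_identical(rep1@switchability$x$switchable, "yes")
  expect_identical(rep1@switchability$x$rule, "cubic-conditions")
  expect_identical(rep1@switchability$y$switchable, "yes")
  # unswitchable output Y (value 9 at both stable states), switchable Z
  rep3 <- analyzeModel("example3")
  expect_identical(rep3@switchability$Y$switchable, "no")
  expect_identical(rep3@switchability$Y$rule, "repeated-root")
  expect_equal(rep3@switchability$Y$outputValues, c(9, 9), tolerance = 1e-10)
  expect_identical(rep3@switchability$Z$switchable, "yes")
  # factorizable network: Z and X switch, Y does not (18 at both stable states)
  rep4 <- analyzeModel("example4")
  expect_identical(rep4@switchability$Z$switchable, "yes")
  expect_identical(rep4@switchability$X$switchable, "yes")
  expect_identical(rep4@switchability$Y$switchable, "no")
  expect_equal(sort(rep4@switchability$Y$outputValues), c(18, 18), tolerance = 1e-9)
  # not bistable: switchability undefined
  one <- analyzeModel(odeSystem("x", c(x = "1 - x")))
  expect_identical(one@switchability$x$switchable, "undefined")
  expect_identical(one@switchability$x$rule, "not-bistable")
})

test_that("rule-based verdicts equal the direct stable-state comparison", {
  # the rules are shortcuts; Definition-style comparison is ground truth
  for (f in c("wilhelm", "edelstein", "example3", "example4", "akt", "mapk", "ras")) {
    rep <- analyzeModel(f)
    if (!identical(rep@verdict$status, "bistable")) next
    rows <- rep@verdict$countedRows
    stable <- rows[rep@states$label[rows] == "stable"]
    for (ov in names(rep@switchability)) {
      sw <- rep@switchability[[ov]]
      vals <- as.numeric(rep@states[stable, ov])
      direct <- abs(vals[1] - vals[2]) > 1e-8 * (1 + max(abs(vals)))
      expect_identical(sw$switchable, if (direct) "yes" else "no",
                       info = paste(f, ov))
    }
  }
})
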