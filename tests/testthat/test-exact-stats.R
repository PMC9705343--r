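# Exact rank tests: worked small-sample values, enumeration-vs-shift
# agreement, external cross-checks and invariances.

test_that("small-sample Mann-Whitney p-values match direct enumeration", {
  expect_equal(pValue(exactMannWhitney(c(1, 2), c(3, 4))), 1 / 3)
  expect_equal(pValue(exactMannWhitney(1:3, 4:6)), 0.1)
  # same multiset in both groups -> p = 1
  expect_equal(pValue(exactMannWhitney(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_error(exactMannWhitney(numeric(0), 1:3), "nonempty")
})

test_that("small-sample signed-rank p-values match direct enumeration", {
  expect_equal(pValue(exactWilcoxonSignedRank(c(2, 3, 4), c(1, 1, 1))), 0.25)
  expect_equal(pValue(exactWilcoxonSignedRank(2, 1)), 1)
  # antisymmetry: swapping the members of every pair leaves p unchanged
  set.seed(4)
  b <- rnorm(8); a <- rnorm(8)
  expect_equal(pValue(exactWilcoxonSignedRank(b, a)),
               pValue(exactWilcoxonSignedRank(a, b)))
  expect_warning(r0 <- exactWilcoxonSignedRank(c(1, 2), c(1, 2)),
                 "zero")
  expect_equal(pValue(r0), 1)
})

test_that("shift recursion equals brute-force enumeration for n <= 9", {
  set.seed(11)
  for (rep in 1:3) {
    for (n1 in 1:4) for (n2 in n1:(9 - n1)) {
      # continuous (tie-free) and heavily tied samples
      xs <- list(rnorm(n1), sample(1:3, n1, replace = TRUE))
      ys <- list(rnorm(n2), sample(1:3, n2, replace = TRUE))
      for (k in 1:2) {
        pShift <- pValue(exactMannWhitney(xs[[k]], ys[[k]],
                                          method = "shift"))
        pEnum <- pValue(exactMannWhitney(xs[[k]], ys[[k]],
                                         method = "enumeration"))
        pOracle <- oracleMWp(xs[[k]], ys[[k]])
        expect_equal(pShift, pEnum, tolerance = 1e-12)
        expect_equal(pShift, pOracle, tolerance = 1e-12)
      }
    }
    for (m in 1:9) {
      b <- rnorm(m); a <- rnorm(m)
      bt <- sample(1:3, m, replace = TRUE); at <- sample(1:3, m,
                                                         replace = TRUE)
      if (all(bt == at)) bt[1] <- bt[1] + 1L
      expect_equal(pValue(exactWilcoxonSignedRank(b, a, enumLimit = 1)),
                   oracleWSRp(b, a), tolerance = 1e-12)
      expect_equal(pValue(exactWilcoxonSignedRank(bt, at, enumLimit = 1)),
                   oracleWSRp(bt, at), tolerance = 1e-12)
    }
  }
})

test_that("tie-free results agree with the reference exact implementation", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    mine <- exactMannWhitney(x, y)
    expect_equal(testStatistic(mine), unname(ref$statistic))
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-9)
    b <- rnorm(7); a <- rnorm(7)
    refP <- stats::wilcox.test(b, a, paired = TRUE, exact = TRUE)
    expect_equal(pValue(exactWilcoxonSignedRank(b, a)), refP$p.value,
                 tolerance = 1e-9)
  }
})

test_that("p-values are invariant under strictly monotone transforms", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(5)
    p0 <- pValue(exactMannWhitney(x, y))
    expect_equal(pValue(exactMannWhitney(exp(x), exp(y))), p0)
    expect_equal(pValue(exactMannWhitney(x^3, y^3)), p0)
  }
})

test_that("median and quartiles match the interpolation oracle", {
  expect_equal(medianIQR(1:5)[["median"]], 3)
  expect_equal(unname(medianIQR(7)), c(7, 7, 7))
  set.seed(17)
  for (i in 1:1000) {
    x <- rnorm(sample(2:30, 1))
    m <- medianIQR(x)
    expect_equal(m[["median"]], oracleQuantile(x, 0.5), tolerance = 1e-12)
    expect_equal(m[["q1"]], oracleQuantile(x, 0.25), tolerance = 1e-12)
    expect_equal(m[["q3"]], oracleQuantile(x, 0.75), tolerance = 1e-12)
  }
  expect_error(medianIQR(numeric(0)), "empty")
})

test_that("large tied designs use the shift path and stay exact", {
  set.seed(23)
  x <- sample(1:4, 12, replace = TRUE)
  y <- sample(1:4, 12, replace = TRUE)
  res <- exactMannWhitney(x, y, enumLimit = 100)
  expect_equal(res@method, "exact-shift")
  expect_true(res@ties)
  expect_equal(pValue(res),
               pValue(exactMannWhitney(x, y, method = "enumeration")),
               tolerance = 1e-12)
})
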