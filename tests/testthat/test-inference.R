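test_that("zero-variance bootstrap input collapses to a point summary", {
  bs <- bootstrapMeanCI(rep(0.47, 6), R = 200, seed = 1)
  expect_equal(bs$mean, 0.47)
  expect_equal(bs$sd, 0)
  expect_equal(c(bs$ciLow, bs$ciHigh), c(0.47, 0.47))
  expect_identical(bs$R, 200L)
})

test_that("n = 2 bootstrap matches the exhaustive resample enumeration", {
  # resamples of {0, 1} with replacement: means 0, 1/2, 1 with probabilities
  # 1/4, 1/2, 1/4; percentile CI hits the extremes
  bs <- bootstrapMeanCI(c(0, 1), R = 20000, seed = 2)
  expect_equal(bs$mean, 0.5)
  expect_equal(c(bs$ciLow, bs$ciHigh), c(0, 1))
  # enumeration oracle for the resample-mean distribution
  set.seed(2)
  draws <- replicate(20000, mean(sample(c(0, 1), 2, replace = TRUE)))
  expect_equal(mean(draws == 0), 0.25, tolerance = 0.02)
  expect_equal(mean(draws == 0.5), 0.5, tolerance = 0.02)
  expect_equal(bs$sd, sqrt(1 / 8), tolerance = 0.02)  # exact SD of the enumeration
})

test_that("bootstrap requests are honoured and permutation-invariant", {
  v <- c(0.1, 0.5, 0.4, 0.9, 0.3, 0.7)
  b1 <- bootstrapMeanCI(v, R = 10000, seed = 3)
  expect_identical(b1$R, 10000L)
  b2 <- bootstrapMeanCI(rev(v), R = 10000, seed = 3)
  expect_equal(b1$mean, b2$mean)
  expect_equal(b1$ciLow, b2$ciLow, tolerance = 0.02)
  expect_equal(b1$ciHigh, b2$ciHigh, tolerance = 0.02)
  expect_error(bootstrapMeanCI(numeric(0)), "empty")
})

test_that("95% percentile CI covers a known mean in most small-sample cohorts", {
  set.seed(4)
  hits <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    v <- rnorm(6, mean = 0.5, sd = 0.1)
    bs <- bootstrapMeanCI(v, R = 400)
    if (bs$ciLow <= 0.5 && 0.5 <= bs$ciHigh) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)  # small-n percentile intervals under-cover
})

test_that("signed-rank test matches enumeration over all sign assignments", {
  # n = 6, all differences positive, untied: two-sided exact p = 2/64
  x <- c(5, 6, 7, 8, 9, 10)
  y <- c(1, 2, 3, 4, 5, 6) - c(0.1, 0.25, 0.4, 0.3, 0.2, 0.15)
  w <- wilcoxonPaired(x, y)
  expect_true(w$exact)
  expect_equal(w$p.value, 2 / 2^6)
  expect_equal(w$statistic, 21)
  # full enumeration oracle on a random untied sample
  set.seed(5)
  d <- rnorm(7)
  w2 <- wilcoxonPaired(d, rep(0, 7))
  rk <- rank(abs(d))
  signs <- expand.grid(rep(list(c(0, 1)), 7))
  vAll <- as.matrix(signs) %*% rk
  vObs <- sum(rk[d > 0])
  pEnum <- min(1, 2 * min(mean(vAll <= vObs), mean(vAll >= vObs)))
  expect_equal(w2$p.value, pEnum)
})

test_that("signed-rank edge cases behave as documented", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(wilcoxonPaired(x, x)$p.value, 1)       # no signal
  y <- x + c(0.3, -0.2, 0.5, -0.1, 0.4, 0.25)
  a <- wilcoxonPaired(x, y)
  b <- wilcoxonPaired(y, x)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$statistic, -b$statistic)             # sign flips on swap
  # zero differences are dropped before ranking
  z <- wilcoxonPaired(c(1, 2, 3, 4), c(1, 2, 2.5, 3.2))
  expect_identical(z$n, 2L)
  # large n falls back to the normal approximation
  set.seed(6)
  big <- wilcoxonPaired(rnorm(40, 0.5), rnorm(40))
  expect_false(big$exact)
  expect_lt(big$p.value, 0.05)
})

test_that("response surfaces honour threshold-contour semantics", {
  set.seed(7)
  cfg <- rescaleDesign(generateLHS(20, 5, seed = 7, nRestarts = 3))
  X <- as.matrix(cfg[, c("cur", "npulses", "pw", "ipp", "del")])
  rg <- parameterRanges()
  # constant surrogate -> flat surface, no contour
  m0 <- fitGPR(X, rep(0, 20), nRestarts = 1, lower = rg)
  s0 <- surfaceResponse(m0, c("pw", "cur"),
                        c(npulses = 4, ipp = 31.25, del = 94), gridRes = 15)
  expect_true(all(s0$z == 0))
  expect_length(s0$contour, 0)
  # everything well above 5% -> the whole plane is beyond the threshold
  m10 <- fitGPR(X, 30 + X[, 1], nRestarts = 2, seed = 8, lower = rg)
  s10 <- surfaceResponse(m10, c("pw", "cur"),
                         c(npulses = 4, ipp = 31.25, del = 94), gridRes = 15)
  expect_true(all(s10$z > 5))
  expect_length(s10$contour, 0)
  # a surface straddling the threshold produces a contour polyline
  mRamp <- fitGPR(X, 25 * (X[, 1] - 0.2) / 0.8, nRestarts = 2, seed = 9,
                  lower = rg)
  sRamp <- surfaceResponse(mRamp, c("pw", "cur"),
                           c(npulses = 4, ipp = 31.25, del = 94), gridRes = 25)
  expect_gt(length(sRamp$contour), 0)
  expect_error(surfaceResponse(m0, c("pw", "pw"), c(npulses = 4, ipp = 31.25,
                                                    del = 94)), "distinct")
  expect_error(surfaceResponse(m0, c("pw", "qq"), c(npulses = 4, ipp = 31.25,
                                                    del = 94)), "distinct|parameter")
})

test_that("selectivity metrics normalize per subject and detect null contrasts", {
  set.seed(10)
  cfg <- rescaleDesign(generateLHS(20, 5, seed = 10, nRestarts = 3))
  X <- as.matrix(cfg[, c("cur", "npulses", "pw", "ipp", "del")])
  rg <- parameterRanges()
  m <- fitGPR(X, 10 * X[, 1], nRestarts = 2, seed = 11, lower = rg)
  s <- surfaceResponse(m, c("npulses", "cur"), c(pw = 0.1, ipp = 31.25, del = 94),
                       gridRes = 12)
  # identical surfaces: p = 1, equal normalized means
  sel <- selectivityMetrics(list(s), list(s))
  expect_equal(sel$p.value, 1)
  expect_equal(sel$chronoPct, sel$inoPct)
  # a surface at its own maximum everywhere scores 100%
  sMax <- s
  sMax$z[] <- max(abs(s$z))
  selMax <- selectivityMetrics(list(sMax), list(s))
  expect_equal(selMax$chronoPct, 100)
  # identically-zero surface scores 0% against a nonzero reference
  sZero <- s
  sZero$z[] <- 0
  selZero <- selectivityMetrics(list(s), list(sZero),
                                inoMax = list(max(abs(s$z))))
  expect_equal(selZero$inoPct, 0)
  # mismatched grids are refused
  sSmall <- surfaceResponse(m, c("npulses", "cur"),
                            c(pw = 0.1, ipp = 31.25, del = 94), gridRes = 8)
  expect_error(selectivityMetrics(list(s), list(sSmall)), "grid")
})
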