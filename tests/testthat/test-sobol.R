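test_that("additive responses give analytic variance fractions and zero interactions", {
  b <- unitBounds(2)
  si <- sobolIndices(function(X) X$x1 + 2 * X$x2, n = 2^13,
                     lower = b$lower, upper = b$upper, seed = 1)
  expect_equal(unname(mainIndices(si)), c(0.2, 0.8), tolerance = 0.02)
  expect_equal(unname(totalIndices(si)), c(0.2, 0.8), tolerance = 0.02)
  expect_lt(max(abs(secondOrderIndices(si))), 0.02)
  expect_equal(interactionIndices(si), totalIndices(si) - mainIndices(si))
})

test_that("a pure-interaction response loads everything on the pair index", {
  b <- unitBounds(2)
  si <- sobolIndices(function(X) (X$x1 - 0.5) * (X$x2 - 0.5), n = 2^14,
                     lower = b$lower, upper = b$upper, seed = 2)
  expect_lt(max(abs(mainIndices(si))), 0.02)
  expect_equal(unname(secondOrderIndices(si)["x1:x2"]), 1, tolerance = 0.05)
  expect_equal(unname(totalIndices(si)), c(1, 1), tolerance = 0.05)
})

test_that("Ishigami indices match the analytic decomposition", {
  a <- 7; bb <- 0.1
  V <- a^2 / 8 + bb * pi^4 / 5 + bb^2 * pi^8 / 18 + 1 / 2
  S1 <- (1 / 2) * (1 + bb * pi^4 / 5)^2 / V
  S2 <- (a^2 / 8) / V
  ST3 <- (8 * bb^2 * pi^8 / 225) / V
  b <- unitBounds(3, -pi, pi)
  si <- sobolIndices(function(X) sin(X$x1) + a * sin(X$x2)^2 +
                       bb * X$x3^4 * sin(X$x1),
                     n = 2^14, lower = b$lower, upper = b$upper, seed = 1)
  m <- mainIndices(si); tt <- totalIndices(si)
  expect_lt(abs(m[["x1"]] - S1), 0.01)
  expect_lt(abs(m[["x2"]] - S2), 0.01)
  expect_lt(abs(m[["x3"]]), 0.01)
  expect_lt(abs(tt[["x3"]] - ST3), 0.01)
  expect_lt(abs(tt[["x2"]] - S2), 0.01)
  # first + second + third order indices of a 3-input function sum to one
  expect_equal(sum(m, secondOrderIndices(si), thirdOrderIndices(si)), 1,
               tolerance = 0.03)
})

test_that("indices are invariant under affine rescaling of the response", {
  b <- unitBounds(3)
  f <- function(X) X$x1 * X$x2 + X$x3
  si1 <- sobolIndices(f, n = 2^12, lower = b$lower, upper = b$upper, seed = 3)
  si2 <- sobolIndices(function(X) -5 * f(X) + 100, n = 2^12,
                      lower = b$lower, upper = b$upper, seed = 3)
  expect_equal(mainIndices(si1), mainIndices(si2), tolerance = 1e-9)
  expect_equal(totalIndices(si1), totalIndices(si2), tolerance = 1e-9)
})

test_that("Monte-Carlo indices match a dense-grid variance decomposition", {
  # 2-input polynomial; oracle: tensor-grid numerical integration of the
  # conditional means
  f <- function(x1, x2) x1^2 + 3 * x1 * x2
  g <- seq(1 / 400, 1 - 1 / 400, length.out = 200)  # midpoint rule
  F <- outer(g, g, f)
  V <- mean((F - mean(F))^2)
  m1 <- rowMeans(F); m2 <- colMeans(F)
  oracle1 <- mean((m1 - mean(F))^2) / V
  oracle2 <- mean((m2 - mean(F))^2) / V
  b <- unitBounds(2)
  si <- sobolIndices(function(X) f(X$x1, X$x2), n = 2^14,
                     lower = b$lower, upper = b$upper, seed = 4)
  expect_lt(abs(mainIndices(si)[["x1"]] - oracle1), 0.01)
  expect_lt(abs(mainIndices(si)[["x2"]] - oracle2), 0.01)
})

test_that("additive total-minus-main gap vanishes at n = 2^14", {
  b <- unitBounds(3)
  si <- sobolIndices(function(X) X$x1 + X$x2 + X$x3, n = 2^14,
                     lower = b$lower, upper = b$upper, seed = 5,
                     orders = c("1", "total"))
  expect_lt(max(abs(interactionIndices(si))), 0.01)
})

test_that("sampled VNS matrices satisfy range and integer-pulse contracts", {
  rg <- parameterRanges()
  mats <- sampleInputMatrices(500, ranges = rg, seed = 6)
  for (M in mats) {
    df <- as.data.frame(M)
    for (p in c("cur", "npulses", "pw", "ipp", "del")) {
      expect_true(all(df[[p]] >= lowerBounds(rg)[p] - 1e-9 &
                        df[[p]] <= upperBounds(rg)[p] + 1e-9))
    }
    expect_true(all(df$npulses %in% 1:4))
  }
  mats2 <- sampleInputMatrices(500, ranges = rg, seed = 6)
  expect_identical(mats, mats2)
})

test_that("a degenerate (constant) response is refused", {
  b <- unitBounds(2)
  expect_error(
    sobolIndices(function(X) rep(1, nrow(X)), n = 256,
                 lower = b$lower, upper = b$upper, seed = 7),
    "degenerate")
})

test_that("effect ranking lists the k largest terms plus a clipped remainder", {
  b <- unitBounds(2)
  siAdd <- sobolIndices(function(X) X$x1 + 2 * X$x2, n = 2^12,
                        lower = b$lower, upper = b$upper, seed = 8)
  rk <- rankEffects(siAdd, k = 5)
  expect_identical(rk$effect[1:2], c("x2", "x1"))
  expect_lt(abs(rk$index[rk$effect == "other"]), 0.05)
  rk0 <- rankEffects(siAdd, k = 0)
  expect_identical(rk0$effect, "other")
  expect_equal(rk0$index, 1)
  siInt <- sobolIndices(function(X) (X$x1 - 0.5) * (X$x2 - 0.5), n = 2^12,
                        lower = b$lower, upper = b$upper, seed = 9)
  rk1 <- rankEffects(siInt, k = 1)
  expect_identical(rk1$effect[1], "x1:x2")
  expect_equal(rk1$index[1], 1, tolerance = 0.05)
})
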