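# independent direct implementation of the Matern 5/2 correlation, used as
# the oracle for the kernel identity
maternOracle <- function(r, ell, sigma2 = 1) {
  sigma2 * (1 + sqrt(5) * r / ell + 5 * r^2 / (3 * ell^2)) * exp(-sqrt(5) * r / ell)
}

test_that("Matern 5/2 kernel matches its closed form on random distances", {
  set.seed(14)
  r <- c(0, runif(999, 0, 10))
  ell <- 1.7
  got <- VNSens:::corrFunction("matern52", r / ell)
  expect_equal(got, maternOracle(r, ell), tolerance = 1e-12)
  # exponential and gaussian families, spot-checked directly
  expect_equal(VNSens:::corrFunction("exponential", 2), exp(-2))
  expect_equal(VNSens:::corrFunction("gaussian", 2), exp(-2))
})

test_that("near-noise-free kriging interpolates its training data", {
  set.seed(2)
  X <- matrix(runif(24, 0, 1), ncol = 2)
  y <- sin(3 * X[, 1]) + X[, 2]^2
  for (fam in c("matern52", "gaussian", "exponential")) {
    m <- fitGPR(X, y, family = fam, nRestarts = 4, seed = 3)
    p <- predict(m, X)
    scale <- diff(range(y))
    expect_lt(max(abs(p$mean - y)) / scale, 1e-3)
    expect_true(all(p$var >= 0))
  }
  # with the nugget pinned at its floor, interpolation is essentially exact
  m <- fitGPR(X, y, family = "matern52", nRestarts = 4, seed = 3,
              nuggetRatio = 1e-8)
  expect_lt(max(abs(predict(m, X)$mean - y)) / diff(range(y)), 1e-6)
})

test_that("constant training data yield a constant predictor", {
  X <- matrix(runif(20), ncol = 2)
  m <- fitGPR(X, rep(7, 10), nRestarts = 2, seed = 1,
              lower = c(0, 0), upper = c(1, 1))
  p <- predict(m, matrix(runif(10), ncol = 2))
  expect_equal(p$mean, rep(7, 5))
  expect_equal(p$var, rep(0, 5))
})

test_that("far-field predictions revert to the stationary prior", {
  set.seed(4)
  X <- matrix(runif(10))
  y <- 2 + sin(5 * X[, 1])
  m <- fitGPR(X, y, nRestarts = 4, seed = 5)
  far <- suppressWarnings(predict(m, matrix(1e6)))
  expect_equal(far$mean, m@mu, tolerance = 1e-8)
  expect_equal(far$var, m@sigma2 + m@nugget, tolerance = 1e-8)
  expect_warning(predict(m, matrix(2)), "extrapolation")
})

test_that("the surrogate beats the constant-mean predictor on a smooth function", {
  f <- function(x) sin(2 * pi * x) + 0.5 * x
  xTrain <- matrix(seq(0, 1, length.out = 10))
  m <- fitGPR(xTrain, f(xTrain[, 1]), nRestarts = 5, seed = 6)
  xDense <- matrix(seq(0, 1, length.out = 400))
  truth <- f(xDense[, 1])
  gprRmse <- sqrt(mean((predict(m, xDense)$mean - truth)^2))
  constRmse <- sqrt(mean((mean(f(xTrain[, 1])) - truth)^2))
  expect_lt(gprRmse, constRmse)
})

test_that("refitting with permuted training order gives identical predictions", {
  set.seed(7)
  X <- matrix(runif(30), ncol = 3)
  y <- X[, 1] + 2 * X[, 2] * X[, 3]
  perm <- sample(nrow(X))
  m1 <- fitGPR(X, y, nRestarts = 1, seed = 8)
  m2 <- fitGPR(X[perm, ], y[perm], nRestarts = 1, seed = 8)
  probe <- matrix(runif(15), ncol = 3)
  expect_equal(predict(m1, probe)$mean, predict(m2, probe)$mean,
               tolerance = 1e-6)
})

test_that("degenerate training inputs are rejected", {
  expect_error(fitGPR(matrix(1:4, 2), c(1, NA)), "non-finite")
  expect_error(fitGPR(matrix(1, 1, 1), 1), "at least 2")
  X <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  expect_error(fitGPR(rbind(X, X[1, ]), c(1, 2, 3, 9)), "conflicting")
})

test_that("rmse matches direct arithmetic", {
  X <- matrix(c(0.1, 0.9))
  m <- fitGPR(matrix(c(0, 0.5, 1)), c(0, 0, 0) + c(1, 2, 3), nRestarts = 2,
              seed = 9)
  p <- predict(m, X)$mean
  y <- p + c(3, -4)
  expect_equal(rmse(m, X, y), sqrt(25 / 2))
  yPerf <- p
  expect_equal(rmse(m, X, yPerf), 0)
  expect_equal(rmse(m, X, p + 2), 2)
  expect_error(rmse(m, matrix(numeric(0)), numeric(0)), "empty")
})

test_that("cross-validation partitions 75 observations 56:19 and is reproducible", {
  set.seed(10)
  X <- matrix(runif(150), ncol = 2)
  y <- X[, 1] + sin(4 * X[, 2])
  cv1 <- crossValidate(X, y, families = c("matern52"), nPartitions = 3,
                       nRestarts = 1, seed = 11)
  expect_identical(cv1@trainSize, 56L)
  expect_identical(cv1@testSize, 19L)
  expect_identical(nrow(cv1@logLik), 3L)
  cv2 <- crossValidate(X, y, families = c("matern52"), nPartitions = 3,
                       nRestarts = 1, seed = 11)
  expect_identical(cv1@logLik, cv2@logLik)
  expect_equal(cv1@rmse, cv2@rmse)
  expect_error(crossValidate(X[1:2, ], y[1:2], nPartitions = 2), "smaller than 2")
})

test_that("family ties resolve in favour of the first declared family", {
  # constant outputs: every family fits the identical degenerate model, so all
  # test log-likelihoods tie exactly
  X <- matrix(runif(40), ncol = 2)
  y <- rep(3, 20)
  cv <- crossValidate(X, y, families = c("exponential", "gaussian", "matern52"),
                      nPartitions = 2, nRestarts = 1, seed = 12)
  expect_identical(cv@winningFamily, "exponential")
  expect_equal(cv@rmse, 0)
})
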