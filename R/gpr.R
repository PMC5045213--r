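GPR_FAMILIES <- c("exponential", "gaussian", "matern52")

# anisotropic scaled Euclidean distance between row sets
scaledDist <- function(X1, X2, lengthScales) {
  A <- sweep(X1, 2, lengthScales, "/")
  B <- sweep(X2, 2, lengthScales, "/")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# stationary correlation functions of the scaled distance r
corrFunction <- function(family, r) {
  switch(family,
    exponential = exp(-r),
    gaussian = exp(-r^2 / 2),
    matern52 = {
      s <- sqrt(5) * r
      (1 + s + s^2 / 3) * exp(-s)
    },
    stop("unknown covariance family: ", family, call. = FALSE)
  )
}

#' Gaussian-process (kriging) surrogate model
#'
#' Constant-mean Gaussian-process regression of a scalar cardiac effect on the
#' stimulation parameters: `y(x) = mu + Z(x)` with `Z` a stationary zero-mean
#' process whose correlation is a function of the anisotropically scaled
#' distance between inputs. Hyperparameters (per-dimension length scales and a
#' small nugget) are estimated by maximum marginal likelihood, with the
#' process variance and mean profiled out.
#'
#' @slot X training input matrix (one row per configuration, physical units).
#' @slot y training outputs (relative effects, %).
#' @slot family covariance family: `"exponential"`, `"gaussian"` or
#'   `"matern52"`.
#' @slot lengthScales per-dimension length scales, in the physical units of
#'   each input.
#' @slot sigma2 process variance ((%)^2).
#' @slot nugget nugget variance ((%)^2, >= 0).
#' @slot mu constant mean (%).
#' @slot logLik maximized log marginal likelihood.
#' @slot L upper Cholesky factor of the correlation matrix plus nugget ratio.
#' @slot alpha cached `R^{-1} (y - mu)`.
#' @slot constant TRUE for the degenerate all-outputs-equal fit.
#' @slot rangeLower,rangeUpper declared input domain (training column ranges
#'   unless explicit bounds were supplied); predictions outside it warn.
#' @export
setClass("GPRModel",
  representation(X = "matrix", y = "numeric", family = "character",
                 lengthScales = "numeric", sigma2 = "numeric",
                 nugget = "numeric", mu = "numeric", logLik = "numeric",
                 L = "matrix", alpha = "numeric", constant = "logical",
                 rangeLower = "numeric", rangeUpper = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (nrow(object@X) != length(object@y)) {
      msgs <- c(msgs, "X and y must have the same number of observations")
    }
    if (length(object@y) < 2) msgs <- c(msgs, "need at least 2 training points")
    if (!object@family %in% GPR_FAMILIES) {
      msgs <- c(msgs, "family must be one of exponential, gaussian, matern52")
    }
    if (any(object@lengthScales <= 0)) msgs <- c(msgs, "length scales must be > 0")
    if (object@sigma2 < 0) msgs <- c(msgs, "process variance must be >= 0")
    if (object@nugget < 0) msgs <- c(msgs, "nugget must be >= 0")
    if (length(msgs)) msgs else TRUE
  }
)

setMethod("show", "GPRModel", function(object) {
  cat(sprintf("Kriging surrogate (%s), %d training points, %d inputs\n",
              object@family, nrow(object@X), ncol(object@X)))
  cat(sprintf("  mean %.3f, process variance %.3f, nugget %.3g, logLik %.2f\n",
              object@mu, object@sigma2, object@nugget, object@logLik))
  ls <- object@lengthScales
  cat("  length scales:", paste(sprintf("%s=%.3g", names(ls), ls), collapse = ", "),
      "\n")
})

# concentrated negative log marginal likelihood; mu and sigma2 profiled out
gprNegLogLik <- function(par, X, y, family, fixedEta = NULL) {
  d <- ncol(X)
  ls <- exp(par[1:d])
  eta <- if (is.null(fixedEta)) exp(par[d + 1]) else fixedEta
  n <- length(y)
  R <- corrFunction(family, scaledDist(X, X, ls))
  diag(R) <- diag(R) + eta
  L <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  ones <- rep(1, n)
  Riy <- backsolve(L, backsolve(L, y, transpose = TRUE))
  Ri1 <- backsolve(L, backsolve(L, ones, transpose = TRUE))
  mu <- sum(Riy) / sum(Ri1)
  r <- y - mu
  sigma2 <- sum(r * (Riy - mu * Ri1)) / n
  if (!is.finite(sigma2) || sigma2 <= 0) return(1e10)
  0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(L))) + n)
}

#' Fit a kriging surrogate by maximum likelihood
#'
#' Estimates per-dimension length scales and the nugget ratio by multi-start
#' L-BFGS-B maximization of the concentrated log marginal likelihood (process
#' variance and constant mean profiled out). Inputs are used in their physical
#' units; length-scale search is scaled to each column's observed range, which
#' is equivalent to standardizing the inputs. The nugget ratio is bounded
#' below at 1e-8 for numerical stability.
#'
#' @param X training inputs: matrix or data.frame (numeric columns only).
#' @param y training outputs (relative effects, %).
#' @param family covariance family (default `"matern52"`).
#' @param nRestarts number of optimizer starts (default 10).
#' @param seed optional integer seed for the random starts.
#' @param lower,upper optional declared input domain (named numeric vectors or
#'   a [ParameterRanges-class] passed as `lower`); defaults to the training
#'   column ranges. Only used to flag extrapolating predictions.
#' @param nuggetRatio fix the nugget-to-process-variance ratio instead of
#'   estimating it (e.g. `1e-8` for essentially noise-free interpolation);
#'   `NULL` (default) estimates it.
#' @return a [GPRModel-class] object.
#' @examples
#' x <- matrix(seq(0, 1, length.out = 10))
#' m <- fitGPR(x, sin(2 * pi * x[, 1]), nRestarts = 3, seed = 1)
#' predict(m, matrix(0.25))
#' @export
fitGPR <- function(X, y, family = c("matern52", "gaussian", "exponential"),
                   nRestarts = 10, seed = NULL, lower = NULL, upper = NULL,
                   nuggetRatio = NULL) {
  family <- match.arg(family)
  if (methods::is(lower, "ParameterRanges")) {
    upper <- lower@upper
    lower <- lower@lower
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ", call. = FALSE)
  if (length(y) < 2) stop("need at least 2 training points", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(X))) {
    stop("non-finite training data", call. = FALSE)
  }
  dup <- duplicated(X) | duplicated(X, fromLast = TRUE)
  if (any(dup)) {
    key <- apply(X, 1, paste, collapse = "\r")
    if (any(tapply(y, key, function(v) diff(range(v)) > 0))) {
      stop("duplicated inputs with conflicting outputs", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  d <- ncol(X)
  colRange <- apply(X, 2, function(v) diff(range(v)))
  colRange[colRange == 0] <- 1
  rngLower <- if (is.null(lower)) apply(X, 2, min) else unname(lower[seq_len(d)])
  rngUpper <- if (is.null(upper)) apply(X, 2, max) else unname(upper[seq_len(d)])
  if (diff(range(y)) == 0) {
    # degenerate constant-output fit: predict the constant everywhere
    return(methods::new("GPRModel", X = X, y = y, family = family,
                        lengthScales = setNames(colRange, colnames(X)),
                        sigma2 = 0, nugget = 0, mu = y[1], logLik = NA_real_,
                        L = diag(n), alpha = rep(0, n), constant = TRUE,
                        rangeLower = rngLower, rangeUpper = rngUpper))
  }
  estimateEta <- is.null(nuggetRatio)
  nPar <- if (estimateEta) d + 1L else d
  # length scales capped at twice the input range: beyond that the kernel is
  # effectively flat, unidentifiable, and numerically near-singular
  optLower <- c(log(colRange) + log(1e-2), if (estimateEta) log(1e-8))
  optUpper <- c(log(colRange) + log(2), if (estimateEta) log(1))
  starts <- vector("list", nRestarts)
  starts[[1]] <- unname(c(log(colRange), if (estimateEta) log(1e-4)))
  if (nRestarts > 1) {
    for (i in 2:nRestarts) {
      starts[[i]] <- unname(c(log(colRange) + runif(d, log(0.1), log(10)),
                              if (estimateEta) runif(1, log(1e-8), log(1e-1))))
    }
  }
  fixedEta <- if (estimateEta) NULL else max(nuggetRatio, 0)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, gprNegLogLik, X = X, y = y, family = family,
            fixedEta = fixedEta,
            method = "L-BFGS-B", lower = optLower, upper = optUpper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("kriging fit failed: covariance matrix singular for all starts",
         call. = FALSE)
  }
  par <- best$par
  ls <- unname(exp(par[1:d]))
  eta <- if (estimateEta) unname(exp(par[d + 1])) else fixedEta
  R <- corrFunction(family, scaledDist(X, X, ls))
  diag(R) <- diag(R) + eta
  L <- chol(R)
  ones <- rep(1, n)
  Riy <- backsolve(L, backsolve(L, y, transpose = TRUE))
  Ri1 <- backsolve(L, backsolve(L, ones, transpose = TRUE))
  mu <- unname(sum(Riy) / sum(Ri1))
  r <- y - mu
  sigma2 <- unname(sum(r * (Riy - mu * Ri1)) / n)
  alpha <- Riy - mu * Ri1
  methods::new("GPRModel", X = X, y = y, family = family,
               lengthScales = setNames(ls, colnames(X)),
               sigma2 = sigma2, nugget = eta * sigma2, mu = mu,
               logLik = -best$value, L = L, alpha = alpha, constant = FALSE,
               rangeLower = rngLower, rangeUpper = rngUpper)
}

#' Kriging prediction
#'
#' Predictive mean and variance at new configurations under the constant-mean
#' model with plug-in hyperparameters. The variance includes the nugget (it is
#' the predictive variance of a new noisy observation) and reverts to process
#' variance plus nugget far from all training points, while the mean reverts
#' to the fitted constant. Predicting outside the training range of any input
#' triggers an extrapolation warning but is allowed.
#'
#' @param object a [GPRModel-class].
#' @param newdata matrix or data.frame of configurations (same columns as the
#'   training inputs).
#' @param ... ignored.
#' @return data.frame with columns `mean` and `var`.
#' @export
setMethod("predict", "GPRModel", function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (!is.null(colnames(Xn)) && all(colnames(object@X) %in% colnames(Xn))) {
    Xn <- Xn[, colnames(object@X), drop = FALSE]
  }
  storage.mode(Xn) <- "double"
  if (ncol(Xn) != ncol(object@X)) {
    stop("newdata must have the same inputs as the training data", call. = FALSE)
  }
  lo <- object@rangeLower
  hi <- object@rangeUpper
  tol <- 1e-8 * (hi - lo)
  if (any(sweep(Xn, 2, lo - tol, "<")) || any(sweep(Xn, 2, hi + tol, ">"))) {
    warning("predicting outside the training input range (extrapolation)",
            call. = FALSE)
  }
  if (object@constant) {
    return(data.frame(mean = rep(object@mu, nrow(Xn)), var = 0))
  }
  C <- corrFunction(object@family, scaledDist(Xn, object@X, object@lengthScales))
  mean <- object@mu + as.numeric(C %*% object@alpha)
  # R^{-1} c via the cached Cholesky factor
  V <- backsolve(object@L, t(C), transpose = TRUE)
  eta <- object@nugget / object@sigma2
  var <- object@sigma2 * pmax(1 + eta - colSums(V^2), 0)
  data.frame(mean = mean, var = var)
})

#' Root-mean-squared prediction error
#'
#' @param model a [GPRModel-class].
#' @param X held-out inputs.
#' @param y held-out outputs.
#' @return RMSE in the units of `y`.
#' @export
rmse <- function(model, X, y) {
  if (length(y) == 0) stop("empty test set", call. = FALSE)
  p <- predict(model, X)
  sqrt(mean((p$mean - y)^2))
}

#' Covariance-family selection by repeated random cross-validation
#'
#' Randomly partitions the observations into a training and a testing group in
#' `trainFraction` proportion (floor of the product; 3:1 by default),
#' `nPartitions` times. For each partition and each candidate family a model
#' is fitted on the training group and scored by the Gaussian predictive
#' log-density of the test outputs. The single (family, partition) fit with
#' the highest test log-likelihood is retained, and its RMSE on its own test
#' split reported. Exact score ties are resolved in favour of the family
#' listed first.
#'
#' @param X input matrix or data.frame.
#' @param y outputs.
#' @param families candidate covariance families, in tie-break order.
#' @param nPartitions number of random partitions (default 1000).
#' @param trainFraction training proportion (default 0.75).
#' @param nRestarts optimizer starts per fit (default 2; the winning model is
#'   refitted exactly as selected, not re-optimized).
#' @param seed optional integer seed.
#' @param lower,upper optional declared input domain (see [fitGPR()]);
#'   defaults to the full-data column ranges.
#' @return a [CVResult-class] object.
#' @export
crossValidate <- function(X, y, families = GPR_FAMILIES, nPartitions = 1000,
                          trainFraction = 0.75, nRestarts = 2, seed = NULL,
                          lower = NULL, upper = NULL) {
  if (methods::is(lower, "ParameterRanges")) {
    upper <- lower@upper
    lower <- lower@lower
  }
  X <- as.matrix(X)
  if (is.null(lower)) lower <- apply(X, 2, min)
  if (is.null(upper)) upper <- apply(X, 2, max)
  y <- as.numeric(y)
  nPartitions <- assertCount(nPartitions, "nPartitions")
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must be in (0, 1)", call. = FALSE)
  }
  families <- match.arg(families, GPR_FAMILIES, several.ok = TRUE)
  n <- length(y)
  nTrain <- floor(trainFraction * n)
  if (nTrain < 2) stop("training split smaller than 2 observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  scores <- matrix(NA_real_, nPartitions, length(families),
                   dimnames = list(NULL, families))
  best <- list(score = -Inf)
  for (p in seq_len(nPartitions)) {
    idx <- sample.int(n, nTrain)
    for (f in families) {
      fit <- tryCatch(
        fitGPR(X[idx, , drop = FALSE], y[idx], family = f,
               nRestarts = nRestarts, lower = lower, upper = upper),
        error = function(e) NULL)
      if (is.null(fit)) next
      pr <- predict(fit, X[-idx, , drop = FALSE])
      sc <- sum(dnorm(y[-idx], pr$mean, sqrt(pmax(pr$var, 1e-12)), log = TRUE))
      scores[p, f] <- sc
      if (is.finite(sc) && sc > best$score) {
        best <- list(score = sc, model = fit, family = f, partition = p,
                     testIdx = setdiff(seq_len(n), idx))
      }
    }
  }
  if (!is.finite(best$score)) stop("all cross-validation fits failed", call. = FALSE)
  methods::new("CVResult",
               logLik = scores, winningFamily = best$family,
               model = best$model,
               rmse = rmse(best$model, X[best$testIdx, , drop = FALSE],
                           y[best$testIdx]),
               nPartitions = nPartitions,
               trainSize = as.integer(nTrain),
               testSize = as.integer(n - nTrain))
}

#' Cross-validation result
#'
#' @slot logLik `nPartitions x families` matrix of test predictive
#'   log-likelihoods.
#' @slot winningFamily selected covariance family.
#' @slot model the retained [GPRModel-class] (fitted on its training split).
#' @slot rmse RMSE of the retained model on its own test split.
#' @slot nPartitions,trainSize,testSize partition bookkeeping.
#' @export
setClass("CVResult",
  representation(logLik = "matrix", winningFamily = "character",
                 model = "GPRModel", rmse = "numeric",
                 nPartitions = "integer", trainSize = "integer",
                 testSize = "integer"),
  validity = function(object) {
    if (nrow(object@logLik) != object@nPartitions) {
      "logLik must have one row per partition"
    } else TRUE
  }
)

setMethod("show", "CVResult", function(object) {
  cat(sprintf("Cross-validation over %d partitions (%d train / %d test):\n",
              object@nPartitions, object@trainSize, object@testSize))
  cat(sprintf("  winner: %s (test logLik %.2f), RMSE %.3f\n",
              object@winningFamily, max(object@logLik, na.rm = TRUE), object@rmse))
})
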