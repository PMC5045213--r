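#' Paired Monte-Carlo input matrices for Sobol estimation
#'
#' Two independent uniform sample matrices over the physical ranges, the base
#' of the paired-matrix (Saltelli) estimation scheme. Integer-valued
#' dimensions (the pulse count, for VNS ranges) are rounded half away from
#' zero after sampling, consistently with the design rescaling, so a surrogate
#' is only ever queried at integer pulse counts.
#'
#' @param n base sample count (>= 2).
#' @param ranges a [ParameterRanges-class], or `NULL` when `lower`/`upper` are
#'   given directly.
#' @param lower,upper named numeric bounds per input (used when `ranges` is
#'   `NULL`).
#' @param seed optional integer seed.
#' @param integerDims names (or indices) of dimensions to round to integers;
#'   defaults to `"npulses"` when `ranges` is supplied.
#' @return list with matrices `A` and `B` (`n x d`, named columns).
#' @export
sampleInputMatrices <- function(n, ranges = NULL, lower = NULL, upper = NULL,
                                seed = NULL, integerDims = NULL) {
  n <- assertCount(n, "n", min = 2L)
  if (!is.null(ranges)) {
    lower <- ranges@lower
    upper <- ranges@upper
    if (is.null(integerDims)) integerDims <- "npulses"
  }
  if (is.null(lower) || is.null(upper)) {
    stop("either 'ranges' or both 'lower' and 'upper' must be given", call. = FALSE)
  }
  d <- length(lower)
  nms <- names(lower)
  if (is.null(nms)) nms <- paste0("x", seq_len(d))
  if (!is.null(seed)) set.seed(seed)
  draw <- function() {
    M <- matrix(runif(n * d), n, d, dimnames = list(NULL, nms))
    M <- sweep(sweep(M, 2, upper - lower, "*"), 2, lower, "+")
    if (!is.null(integerDims)) {
      for (k in integerDims) M[, k] <- roundHalfAwayFromZero(M[, k])
    }
    M
  }
  list(A = draw(), B = draw())
}

#' Sobol sensitivity indices of a response function
#'
#' Monte-Carlo estimation of the variance-based sensitivity decomposition of a
#' scalar response over independent uniform inputs: main (first-order) and
#' total indices per input, and optionally pure second- and third-order
#' interaction indices, all normalized by the output variance so each effect
#' lies in `[0, 1]` up to Monte-Carlo noise. Small negative estimates are
#' reported as-is, not clipped.
#'
#' Estimators follow the full symmetric Saltelli paired-matrix scheme: for
#' each subset `u` of inputs both mixed matrices are formed -- `AB_u` (columns
#' in `u` from `B`, rest from `A`) and its mirror `BA_u` -- and the two half
#' estimates are averaged, halving the Monte-Carlo variance. With
#' `V = Var[y]` pooled over `A` and `B` and all evaluations centred:
#' * closed index of `u` (Saltelli/Sobol):
#'   `(mean(f(B) (f(AB_u) - f(A))) + mean(f(A) (f(BA_u) - f(B)))) / (2 V)`;
#'   first-order indices are the singleton case, and pure second/third-order
#'   interaction terms subtract all lower-order contributions.
#' * total (Jansen):
#'   `(mean((f(A) - f(AB_i))^2) + mean((f(B) - f(BA_i))^2)) / (4 V)`
#'
#' @param response the function to analyze: either a function taking a
#'   data.frame of configurations (named columns) and returning a numeric
#'   vector, or a [GPRModel-class] whose predictive mean is used.
#' @param n base sample count; each of the `2 + d (+ pairs + triples)`
#'   matrices has `n` rows.
#' @param ranges a [ParameterRanges-class], or `NULL` with explicit
#'   `lower`/`upper`.
#' @param lower,upper named numeric bounds when `ranges` is `NULL`.
#' @param seed optional integer seed.
#' @param orders subset of `c("1", "2", "3", "total")` (numeric accepted).
#' @param integerDims see [sampleInputMatrices()].
#' @return a [SensitivityIndices-class] object.
#' @examples
#' si <- sobolIndices(function(X) X$x1 + 2 * X$x2, n = 4096,
#'                    lower = c(x1 = 0, x2 = 0), upper = c(x1 = 1, x2 = 1),
#'                    seed = 1, orders = c("1", "total"))
#' mainIndices(si)  # about 0.2 and 0.8
#' @export
sobolIndices <- function(response, n, ranges = NULL, lower = NULL, upper = NULL,
                         seed = NULL, orders = c("1", "2", "3", "total"),
                         integerDims = NULL) {
  orders <- as.character(orders)
  bad <- setdiff(orders, c("1", "2", "3", "total"))
  if (length(bad)) stop("unknown orders: ", paste(bad, collapse = ", "), call. = FALSE)
  if (methods::is(response, "GPRModel")) {
    model <- response
    response <- function(X) predict(model, X)$mean
  }
  mats <- sampleInputMatrices(n, ranges, lower, upper, seed, integerDims)
  A <- mats$A
  B <- mats$B
  d <- ncol(A)
  nms <- colnames(A)
  needPairs <- any(c("2", "3") %in% orders) && d >= 2
  needTriples <- "3" %in% orders && d >= 3
  subsets <- lapply(seq_len(d), identity)
  if (needPairs) subsets <- c(subsets, combnList(d, 2))
  if (needTriples) subsets <- c(subsets, combnList(d, 3))
  mixed <- lapply(subsets, function(u) {
    AB <- A
    AB[, u] <- B[, u, drop = FALSE]
    BA <- B
    BA[, u] <- A[, u, drop = FALSE]
    list(AB, BA)
  })
  blocks <- c(list(A, B), unlist(mixed, recursive = FALSE))
  f <- response(as.data.frame(do.call(rbind, blocks)))
  if (length(f) != length(blocks) * n || any(!is.finite(f))) {
    stop("response must return one finite value per configuration", call. = FALSE)
  }
  fs <- lapply(seq_along(blocks), function(j) f[((j - 1) * n + 1):(j * n)])
  fA <- fs[[1]]
  fB <- fs[[2]]
  V <- var(c(fA, fB))
  f0 <- mean(c(fA, fB))
  if (!is.finite(V) || V <= 0) {
    stop("degenerate response: zero output variance, indices undefined",
         call. = FALSE)
  }
  # centre the evaluations before forming the product estimators (standard
  # variance reduction; leaves the estimators' expectations unchanged)
  fs <- lapply(fs, function(v) v - f0)
  fA <- fs[[1]]
  fB <- fs[[2]]
  fAB <- function(j) fs[[2 * j + 1]]
  fBA <- function(j) fs[[2 * j + 2]]
  closed <- vapply(seq_along(subsets), function(j) {
    (mean(fB * (fAB(j) - fA)) + mean(fA * (fBA(j) - fB))) / (2 * V)
  }, numeric(1))
  main <- setNames(closed[seq_len(d)], nms)
  total <- setNames(vapply(seq_len(d), function(i) {
    (mean((fA - fAB(i))^2) + mean((fB - fBA(i))^2)) / (4 * V)
  }, numeric(1)), nms)
  second <- numeric(0)
  third <- numeric(0)
  if (needPairs) {
    pairs <- subsets[(d + 1):(d + choose(d, 2))]
    second <- setNames(vapply(seq_along(pairs), function(j) {
      u <- pairs[[j]]
      closed[d + j] - sum(main[u])
    }, numeric(1)), vapply(pairs, function(u) paste(nms[u], collapse = ":"), ""))
  }
  if (needTriples) {
    off <- d + choose(d, 2)
    triples <- subsets[(off + 1):(off + choose(d, 3))]
    pairName <- function(u) paste(nms[u], collapse = ":")
    third <- setNames(vapply(seq_along(triples), function(j) {
      u <- triples[[j]]
      prs <- combnList(3, 2)
      closed[off + j] - sum(main[u]) -
        sum(vapply(prs, function(p) second[pairName(u[p])], numeric(1)))
    }, numeric(1)), vapply(triples, pairName, ""))
  }
  methods::new("SensitivityIndices",
               variance = V, mean = f0,
               main = main, total = total,
               second = second, third = third,
               interactions = total - main,
               nSamples = as.integer(n),
               nEvaluations = as.integer(length(blocks)) * as.integer(n),
               orders = orders,
               seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

combnList <- function(d, k) {
  m <- utils::combn(d, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Sobol variance decomposition of a response
#'
#' @slot variance total output variance.
#' @slot mean output mean.
#' @slot main first-order index per input.
#' @slot total total index per input.
#' @slot second pure second-order interaction index per pair (`"a:b"` names).
#' @slot third pure third-order interaction index per triple.
#' @slot interactions `total - main` per input (exact identity).
#' @slot nSamples base Monte-Carlo sample count.
#' @slot nEvaluations total response evaluations performed.
#' @slot orders which orders were estimated.
#' @slot seed the seed used (NA when none was set).
#' @export
setClass("SensitivityIndices",
  representation(variance = "numeric", mean = "numeric", main = "numeric",
                 total = "numeric", second = "numeric", third = "numeric",
                 interactions = "numeric", nSamples = "integer",
                 nEvaluations = "integer", orders = "character",
                 seed = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (!identical(names(object@main), names(object@total))) {
      msgs <- c(msgs, "main and total must cover the same inputs")
    }
    if (max(abs(object@interactions - (object@total - object@main))) > 1e-12) {
      msgs <- c(msgs, "interactions must equal total - main")
    }
    if (object@variance <= 0) msgs <- c(msgs, "variance must be > 0")
    if (length(msgs)) msgs else TRUE
  }
)

setMethod("show", "SensitivityIndices", function(object) {
  cat(sprintf("Sobol indices (base n = %d, %d evaluations, variance %.4g):\n",
              object@nSamples, object@nEvaluations, object@variance))
  tab <- data.frame(main = round(object@main, 4), total = round(object@total, 4),
                    interactions = round(object@interactions, 4))
  print(tab)
  if (length(object@second)) {
    top <- sort(object@second, decreasing = TRUE)
    cat("  top second-order:",
        paste(sprintf("%s=%.4f", names(top)[1:min(3, length(top))],
                      top[1:min(3, length(top))]), collapse = ", "), "\n")
  }
})

#' @describeIn sobolIndices main (first-order) indices of a fitted object.
#' @param indices a [SensitivityIndices-class].
#' @export
mainIndices <- function(indices) indices@main

#' @describeIn sobolIndices total indices.
#' @export
totalIndices <- function(indices) indices@total

#' @describeIn sobolIndices interaction strengths (`total - main`).
#' @export
interactionIndices <- function(indices) indices@interactions

#' @describeIn sobolIndices pure second-order indices.
#' @export
secondOrderIndices <- function(indices) indices@second

#' @describeIn sobolIndices pure third-order indices.
#' @export
thirdOrderIndices <- function(indices) indices@third

#' Rank the largest first-, second- and third-order effects
#'
#' Collects all estimated first-, second- and third-order indices, orders them
#' decreasingly, keeps the `k` largest, and sums the remainder into an
#' `"other"` row computed as `1 -` the sum of the listed indices, clipped at
#' zero.
#'
#' @param indices a [SensitivityIndices-class] computed with orders 1, 2, 3.
#' @param k number of effects to list (default 5).
#' @return data.frame with columns `effect`, `order`, `index`; the last row is
#'   `"other"`.
#' @export
rankEffects <- function(indices, k = 5) {
  k <- assertCount(k, "k", min = 0L)
  all <- c(indices@main, indices@second, indices@third)
  ord <- c(rep(1L, length(indices@main)), rep(2L, length(indices@second)),
           rep(3L, length(indices@third)))
  o <- order(all, decreasing = TRUE)
  keep <- o[seq_len(min(k, length(all)))]
  data.frame(
    effect = c(names(all)[keep], "other"),
    order = c(ord[keep], NA_integer_),
    index = c(unname(all[keep]), max(0, 1 - sum(all[keep])))
  )
}
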