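#' Percentile-bootstrap summary of per-subject values
#'
#' With-replacement resampling of the input values (`R` resamples of the
#' original size), summarizing the resampled means: the point estimate is the
#' plain mean of the inputs, the bootstrap SD is the standard deviation of the
#' resample means, and the 95% interval is their 2.5th/97.5th percentile.
#'
#' @param values numeric vector (one value per subject; >= 1).
#' @param R number of resamples (default 10000).
#' @param seed optional integer seed.
#' @return object of class `vns_bootstrap`: list with `mean`, `sd`, `ciLow`,
#'   `ciHigh`, `R`, `seed`.
#' @export
bootstrapMeanCI <- function(values, R = 10000, seed = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("empty input", call. = FALSE)
  R <- assertCount(R, "R")
  if (!is.null(seed)) set.seed(seed)
  # resampling the sorted values makes the summary exactly invariant to the
  # input order (the mean is exchangeable in its arguments)
  values <- sort(values)
  if (diff(range(values)) == 0) {
    out <- list(mean = values[1], sd = 0, ciLow = values[1], ciHigh = values[1],
                R = R, seed = seed)
  } else {
    bt <- boot::boot(values, function(d, i) mean(d[i]), R = R)
    ci <- quantile(bt$t[, 1], c(0.025, 0.975), names = FALSE)
    out <- list(mean = mean(values), sd = sd(bt$t[, 1]),
                ciLow = ci[1], ciHigh = ci[2], R = R, seed = seed)
  }
  structure(out, class = "vns_bootstrap")
}

#' @export
print.vns_bootstrap <- function(x, ...) {
  cat(sprintf("mean %.4f (bootstrap sd %.4f), 95%% CI [%.4f, %.4f], R = %d\n",
              x$mean, x$sd, x$ciLow, x$ciHigh, x$R))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are dropped
#' (standard signed-rank convention). For 15 or fewer non-zero differences
#' with untied absolute values the exact null distribution of the rank sum is
#' used; otherwise a normal approximation with tie correction. The reported
#' statistic is the signed rank sum `V+ - V-`, so swapping the samples flips
#' its sign while leaving the p-value unchanged.
#'
#' @param x,y paired numeric samples of equal length (>= 2).
#' @return list with `statistic` (signed rank sum), `p.value`, `n` (non-zero
#'   pairs) and `exact` (logical).
#' @export
wilcoxonPaired <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p.value = 1, n = 0L, exact = TRUE))
  }
  rk <- rank(abs(d))
  vPlus <- sum(rk[d > 0])
  statistic <- vPlus - sum(rk[d < 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 15 && !ties) {
    pLower <- psignrank(vPlus, n)
    pUpper <- 1 - psignrank(vPlus - 1, n)
    p <- min(1, 2 * min(pLower, pUpper))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48
    z <- (vPlus - mu) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = statistic, p.value = p, n = as.integer(n), exact = exact)
}

#' Predicted-effect surface over a pair of parameters
#'
#' Evaluates a fitted surrogate on a dense grid over the physical ranges of
#' two parameters, the remaining three held at fixed values, and extracts the
#' contour where the predicted effect magnitude crosses a reference threshold
#' (5% of baseline by default) by marching squares with linear interpolation.
#'
#' @param model a [GPRModel-class] trained on the five VNS parameters.
#' @param pair character(2): the varying parameters (e.g. `c("pw", "cur")`).
#' @param fixed named numeric values for the remaining three parameters.
#' @param ranges a [ParameterRanges-class].
#' @param gridRes grid resolution per axis (default 50).
#' @param threshold contour level, percent of baseline (default 5).
#' @return object of class `vns_surface`: list with `pair`, `fixed`, `x`, `y`
#'   (axis values), `z` (`gridRes x gridRes` matrix of predicted effects, %),
#'   `contour` (list of data.frames with the threshold polylines, possibly
#'   empty), `threshold`.
#' @export
surfaceResponse <- function(model, pair, fixed, ranges = parameterRanges(),
                            gridRes = 50, threshold = 5) {
  pair <- as.character(pair)
  if (length(pair) != 2 || pair[1] == pair[2] || !all(pair %in% VNS_PARAMS)) {
    stop("'pair' must name two distinct VNS parameters", call. = FALSE)
  }
  rest <- setdiff(VNS_PARAMS, pair)
  if (!all(rest %in% names(fixed))) {
    stop("'fixed' must provide values for: ", paste(rest, collapse = ", "),
         call. = FALSE)
  }
  fixed <- fixed[rest]
  bad <- fixed < ranges@lower[rest] | fixed > ranges@upper[rest]
  if (any(bad)) {
    stop("fixed value out of range for: ", paste(rest[bad], collapse = ", "),
         call. = FALSE)
  }
  gridRes <- assertCount(gridRes, "gridRes", min = 2L)
  ax <- lapply(pair, function(p) {
    seq(ranges@lower[p], ranges@upper[p], length.out = gridRes)
  })
  grid <- expand.grid(x = ax[[1]], y = ax[[2]])
  df <- data.frame(matrix(rep(unname(fixed), each = nrow(grid)), nrow(grid)))
  names(df) <- rest
  df[[pair[1]]] <- grid$x
  df[[pair[2]]] <- grid$y
  if ("npulses" %in% pair) df$npulses <- roundHalfAwayFromZero(df$npulses)
  pred <- predict(model, df[, VNS_PARAMS])
  z <- matrix(pred$mean, gridRes, gridRes)
  cl <- grDevices::contourLines(ax[[1]], ax[[2]], abs(z), levels = threshold)
  contour <- lapply(cl, function(c0) data.frame(x = c0$x, y = c0$y))
  structure(list(pair = pair, fixed = fixed, x = ax[[1]], y = ax[[2]], z = z,
                 contour = contour, threshold = threshold),
            class = "vns_surface")
}

#' @export
print.vns_surface <- function(x, ...) {
  cat(sprintf("Response surface %s x %s (%dx%d), effect %.1f..%.1f%%, %d contour line(s) at %g%%\n",
              x$pair[1], x$pair[2], length(x$x), length(x$y),
              min(x$z), max(x$z), length(x$contour), x$threshold))
  invisible(x)
}

#' Functional-selectivity metrics between two cardiac effects
#'
#' Compares matched response surfaces of two cardiac effects (typically
#' chronotropic vs inotropic on the pulse-count x current plane): each
#' subject's surface is normalized by that subject's maximum response
#' magnitude (its own surface maximum by default, or an externally supplied
#' reference, e.g. the subject's maximum response over the whole parameter
#' domain), the normalized magnitudes are averaged, and the two effects are
#' compared by a paired signed-rank test over matched grid cells pooled
#' across subjects.
#'
#' @param chronoSurfaces,inoSurfaces lists of `vns_surface` (one per subject)
#'   on identical grids.
#' @param chronoMax,inoMax optional per-subject normalization references
#'   (maximum response magnitude, %); default is each surface's own maximum.
#' @return list with `chronoPct` and `inoPct` (mean normalized response in
#'   percent of the maximum), `p.value`, and `perSubject` (data.frame).
#' @export
selectivityMetrics <- function(chronoSurfaces, inoSurfaces,
                               chronoMax = NULL, inoMax = NULL) {
  if (length(chronoSurfaces) != length(inoSurfaces)) {
    stop("need one chronotropic and one inotropic surface per subject",
         call. = FALSE)
  }
  norm <- function(s, ref) {
    m <- if (is.null(ref)) max(abs(s$z)) else ref
    if (m == 0) array(0, dim(s$z)) else abs(s$z) / m
  }
  chronoN <- list()
  inoN <- list()
  for (i in seq_along(chronoSurfaces)) {
    cs <- chronoSurfaces[[i]]
    is_ <- inoSurfaces[[i]]
    if (!identical(dim(cs$z), dim(is_$z)) ||
        !isTRUE(all.equal(cs$x, is_$x)) || !isTRUE(all.equal(cs$y, is_$y))) {
      stop("mismatched grids between chronotropic and inotropic surfaces",
           call. = FALSE)
    }
    chronoN[[i]] <- norm(cs, if (is.null(chronoMax)) NULL else chronoMax[[i]])
    inoN[[i]] <- norm(is_, if (is.null(inoMax)) NULL else inoMax[[i]])
  }
  perSubject <- data.frame(
    subject = seq_along(chronoN),
    chronoPct = 100 * vapply(chronoN, mean, numeric(1)),
    inoPct = 100 * vapply(inoN, mean, numeric(1))
  )
  test <- wilcoxonPaired(unlist(chronoN), unlist(inoN))
  list(chronoPct = mean(perSubject$chronoPct),
       inoPct = mean(perSubject$inoPct),
       p.value = test$p.value,
       perSubject = perSubject)
}
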