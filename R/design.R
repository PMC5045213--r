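#' Optimized Latin hypercube design in the unit hypercube
#'
#' Draws `nRestarts` random Latin hypercube designs of `n` points in `d`
#' dimensions and keeps the one with the largest mean pairwise Euclidean
#' distance, a space-filling criterion that spreads the points evenly while
#' preserving the Latin (one point per axis-aligned stratum) property.
#'
#' @param n number of design points (>= 1).
#' @param d number of dimensions (>= 1).
#' @param seed integer seed; the returned design is bit-identical for a given
#'   seed.
#' @param nRestarts number of random candidates scored (default 1000).
#' @return an object of class `vns_unit_design`: a list with `points` (an
#'   `n x d` matrix in `[0,1]`), `score` (mean pairwise distance of the
#'   retained design; 0 for a single point), `candidateScores` (the scores of
#'   all candidates, retained one included), `seed` and `nRestarts`.
#' @examples
#' des <- generateLHS(5, 2, seed = 1, nRestarts = 10)
#' des$score
#' @export
generateLHS <- function(n, d, seed = NULL, nRestarts = 1000) {
  n <- assertCount(n, "n")
  d <- assertCount(d, "d")
  nRestarts <- assertCount(nRestarts, "nRestarts")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  bestScore <- -Inf
  scores <- numeric(nRestarts)
  for (r in seq_len(nRestarts)) {
    cand <- lhs::randomLHS(n, d)
    sc <- if (n > 1) mean(dist(cand)) else 0
    scores[r] <- sc
    if (sc > bestScore) {
      bestScore <- sc
      best <- cand
    }
  }
  structure(
    list(points = best, score = bestScore, candidateScores = scores,
         seed = seed, nRestarts = nRestarts),
    class = "vns_unit_design"
  )
}

#' @export
print.vns_unit_design <- function(x, ...) {
  cat(sprintf("Latin hypercube design: %d points x %d dims, mean pairwise distance %.4f (best of %d candidates)\n",
              nrow(x$points), ncol(x$points), x$score, x$nRestarts))
  invisible(x)
}

#' Rescale a unit design to physical VNS configurations
#'
#' Maps each unit coordinate `u` to `min + u * (max - min)` on the matching
#' parameter axis, in the canonical order `cur, npulses, pw, ipp, del`. The
#' pulse count is rounded to the nearest integer after rescaling, half away
#' from zero (so a rescaled 2.5 becomes 3 pulses).
#'
#' @param design a `vns_unit_design` with `d = 5`, or a bare `n x 5` matrix of
#'   unit coordinates.
#' @param ranges a [ParameterRanges-class] object.
#' @return a data.frame with columns `id, cur, npulses, pw, ipp, del`; one row
#'   per configuration.
#' @export
rescaleDesign <- function(design, ranges = parameterRanges()) {
  pts <- if (inherits(design, "vns_unit_design")) design$points else as.matrix(design)
  if (ncol(pts) != length(VNS_PARAMS)) {
    stop(sprintf("design must have %d columns (one per VNS parameter), got %d",
                 length(VNS_PARAMS), ncol(pts)), call. = FALSE)
  }
  if (any(pts < 0 | pts > 1)) {
    stop("unit design coordinates must lie in [0, 1]", call. = FALSE)
  }
  lo <- ranges@lower
  hi <- ranges@upper
  out <- data.frame(id = sprintf("S%02d", seq_len(nrow(pts))))
  for (k in seq_along(VNS_PARAMS)) {
    out[[VNS_PARAMS[k]]] <- lo[k] + pts[, k] * (hi[k] - lo[k])
  }
  out$npulses <- roundHalfAwayFromZero(out$npulses)
  out
}

#' Map physical configurations back to unit coordinates
#'
#' Inverse of the affine part of [rescaleDesign()]; pulse-count rounding is not
#' invertible, so the integer count maps to its exact unit coordinate.
#'
#' @param configs data.frame of configurations.
#' @param ranges a [ParameterRanges-class] object.
#' @return matrix of unit coordinates.
#' @export
unitCoordinates <- function(configs, ranges = parameterRanges()) {
  df <- asConfigFrame(configs)
  sapply(VNS_PARAMS, function(p) {
    (df[[p]] - ranges@lower[p]) / (ranges@upper[p] - ranges@lower[p])
  })
}

# CSV serialisation; header uses explicit physical units
DESIGN_CSV_NAMES <- c(id = "id", cur = "cur_mA", npulses = "npulses",
                      pw = "pw_ms", ipp = "ipp_ms", del = "del_ms")

#' Write or read a design CSV
#'
#' The on-disk header is `id,cur_mA,npulses,pw_ms,ipp_ms,del_ms`; one row per
#' configuration.
#'
#' @param configs data.frame of configurations as returned by [rescaleDesign()].
#' @param path output file path.
#' @export
writeDesignCSV <- function(configs, path) {
  df <- configs[, names(DESIGN_CSV_NAMES)]
  names(df) <- unname(DESIGN_CSV_NAMES)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDesignCSV
#' @export
readDesignCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(DESIGN_CSV_NAMES), names(df))
  if (length(missing)) {
    stop("design CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- df[, unname(DESIGN_CSV_NAMES)]
  names(out) <- names(DESIGN_CSV_NAMES)
  out
}
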