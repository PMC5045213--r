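#' Physical ranges of the five VNS burst parameters
#'
#' An S4 container for the admissible interval of each stimulation parameter:
#' current amplitude (`cur`, mA), number of pulses (`npulses`), pulse width
#' (`pw`, ms), interpulse period (`ipp`, ms) and the delay between the detected
#' cardiac event and burst onset (`del`, ms). Every lower bound must be
#' strictly positive and strictly below its upper bound.
#'
#' @slot lower named numeric vector of lower bounds, in the canonical order
#'   `cur, npulses, pw, ipp, del`.
#' @slot upper named numeric vector of upper bounds, same order.
#' @export
setClass("ParameterRanges",
  representation(lower = "numeric", upper = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (!identical(names(object@lower), VNS_PARAMS) ||
        !identical(names(object@upper), VNS_PARAMS)) {
      msgs <- c(msgs, sprintf("bounds must be named %s, in that order",
                              paste(VNS_PARAMS, collapse = ", ")))
    }
    if (any(!is.finite(object@lower)) || any(!is.finite(object@upper))) {
      msgs <- c(msgs, "all bounds must be finite")
    } else {
      if (any(object@lower <= 0)) msgs <- c(msgs, "all lower bounds must be > 0")
      if (any(object@lower >= object@upper)) {
        msgs <- c(msgs, "every lower bound must be < its upper bound")
      }
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct stimulation-parameter ranges
#'
#' Defaults are the protocol ranges used throughout the package: 0.2--1 mA
#' current, 1--4 pulses, 0.05--0.20 ms pulse width, 24.4--47 ms interpulse
#' period and 16--156 ms onset delay.
#'
#' @param cur,npulses,pw,ipp,del length-2 numeric `c(min, max)` per parameter.
#' @return a [ParameterRanges-class] object.
#' @examples
#' rg <- parameterRanges()
#' upperBounds(rg)["cur"]  # 1 mA
#' @export
parameterRanges <- function(cur = c(0.2, 1), npulses = c(1, 4),
                            pw = c(0.05, 0.20), ipp = c(24.4, 47),
                            del = c(16, 156)) {
  b <- rbind(cur = cur, npulses = npulses, pw = pw, ipp = ipp, del = del)
  methods::new("ParameterRanges",
               lower = setNames(b[, 1], VNS_PARAMS),
               upper = setNames(b[, 2], VNS_PARAMS))
}

#' @describeIn parameterRanges lower bounds, named by parameter.
#' @param ranges a `ParameterRanges` object.
#' @export
lowerBounds <- function(ranges) ranges@lower

#' @describeIn parameterRanges upper bounds, named by parameter.
#' @export
upperBounds <- function(ranges) ranges@upper

setMethod("show", "ParameterRanges", function(object) {
  units <- c(cur = "mA", npulses = "pulses", pw = "ms", ipp = "ms", del = "ms")
  cat("VNS stimulation parameter ranges:\n")
  for (p in VNS_PARAMS) {
    cat(sprintf("  %-8s %g to %g %s\n", p, object@lower[p], object@upper[p], units[p]))
  }
})

# TRUE for each row of a config frame lying inside the ranges
inRanges <- function(config, ranges, tol = 1e-9) {
  df <- asConfigFrame(config)
  ok <- rep(TRUE, nrow(df))
  for (p in VNS_PARAMS) {
    ok <- ok & df[[p]] >= ranges@lower[p] - tol & df[[p]] <= ranges@upper[p] + tol
  }
  ok
}
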