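#' @importFrom stats dist dnorm median optim plogis pnorm psignrank quantile
#'   rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

# canonical order of the five burst parameters (current, pulse count, pulse
# width, interpulse period, onset delay)
VNS_PARAMS <- c("cur", "npulses", "pw", "ipp", "del")

#' Round half away from zero
#'
#' Commercial rounding used wherever a sampled pulse count must be mapped to an
#' integer: 2.5 becomes 3, -2.5 becomes -3. `base::round()` rounds half to
#' even, which would silently bias the pulse-count distribution.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
roundHalfAwayFromZero <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assertNumber <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min) {
    stop(sprintf("'%s' must be a single finite number >= %s", name, format(min)),
         call. = FALSE)
  }
  as.numeric(x)
}

# coerce a configuration (named vector, list, or data.frame) to a data.frame
# with the canonical parameter columns
asConfigFrame <- function(config) {
  if (is.data.frame(config)) {
    df <- config
  } else if (is.list(config) || (is.numeric(config) && !is.null(names(config)))) {
    df <- as.data.frame(as.list(config))
  } else {
    stop("configuration must be a named vector, list or data.frame", call. = FALSE)
  }
  missing <- setdiff(VNS_PARAMS, names(df))
  if (length(missing)) {
    stop("configuration is missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}
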