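getMarkerSeries <- function(beats, marker = NULL) {
  if (is.data.frame(beats)) {
    if (is.null(marker)) stop("'marker' is required when passing a beat table",
                              call. = FALSE)
    if (!marker %in% names(beats)) {
      stop(sprintf("unknown marker '%s'", marker), call. = FALSE)
    }
    beats[[marker]]
  } else {
    as.numeric(beats)
  }
}

#' Baseline marker value of the rest period
#'
#' Arithmetic mean of the marker over the last ten beats of the off period.
#'
#' @param beats numeric marker series, or a beat data.frame plus `marker`.
#' @param marker column name when `beats` is a data.frame.
#' @return baseline value, in the marker's units.
#' @export
baselineValue <- function(beats, marker = NULL) {
  x <- getMarkerSeries(beats, marker)
  if (length(x) < 10) {
    stop(sprintf("insufficient baseline: need >= 10 off-period beats, got %d",
                 length(x)), call. = FALSE)
  }
  mean(x[(length(x) - 9):length(x)])
}

#' Stimulation-period marker value
#'
#' Median of the marker over beats 4 to 23 (1-based, inclusive: 20 beats) of
#' the on period; the first three beats are excluded to skip the transient
#' response. If fewer than 23 on beats are available, the window is truncated
#' to beats 4..last with a warning; fewer than 4 beats is an error.
#'
#' @inheritParams baselineValue
#' @return stimulation value, in the marker's units.
#' @export
stimValue <- function(beats, marker = NULL) {
  x <- getMarkerSeries(beats, marker)
  if (length(x) < 4) {
    stop(sprintf("insufficient stimulation period: need >= 4 on-period beats, got %d",
                 length(x)), call. = FALSE)
  }
  last <- min(length(x), 23L)
  if (length(x) < 23) {
    warning(sprintf("on period has %d beats (< 23); stimulation window truncated to beats 4..%d",
                    length(x), last), call. = FALSE)
  }
  median(x[4:last])
}

#' Relative cardiac effect of one sequence
#'
#' Signed percent change of the stimulation value with respect to baseline:
#' `100 * (stim - baseline) / baseline`.
#'
#' @param offBeats off-period marker series (or beat data.frame).
#' @param onBeats on-period marker series (or beat data.frame).
#' @param marker column name when data.frames are passed.
#' @return relative effect in percent.
#' @export
relativeEffect <- function(offBeats, onBeats, marker = NULL) {
  b <- baselineValue(offBeats, marker)
  if (b == 0) stop("baseline value is zero; relative effect undefined", call. = FALSE)
  s <- stimValue(onBeats, marker)
  100 * (s - b) / b
}

#' Apply the exclusion rules and compute per-configuration effects
#'
#' A sequence is excluded when its adverse-event flag is set, its bradycardia
#' flag is set, or any on-period RR interval is strictly greater than
#' `rrLimit` (1100 ms by default; an RR of exactly 1100 ms is kept). Included
#' sequences yield the three relative effects.
#'
#' @param sequences list of `vns_sequence` objects.
#' @param rrLimit bradycardia threshold in ms (> 0).
#' @return data.frame with one row per sequence: `subject, config_id`, the
#'   five parameter columns, `y_rr, y_pr, y_dpdt` (percent; `NA` when
#'   excluded), `included`, `reason` (`""`, `"adverse"` or `"bradycardia"`).
#' @export
applyExclusions <- function(sequences, rrLimit = 1100) {
  rrLimit <- assertNumber(rrLimit, "rrLimit", min = .Machine$double.eps)
  rows <- lapply(sequences, function(s) {
    reason <- ""
    if (isTRUE(s$adverse)) {
      reason <- "adverse"
    } else if (isTRUE(s$bradycardia) || any(s$on$rr > rrLimit)) {
      reason <- "bradycardia"
    }
    included <- reason == ""
    eff <- c(rr = NA_real_, pr = NA_real_, dpdt = NA_real_)
    if (included) {
      eff <- vapply(c("rr", "pr", "dpdt"), function(m) {
        relativeEffect(s$off, s$on, m)
      }, numeric(1))
    }
    cfg <- s$config
    data.frame(subject = s$subject,
               config_id = s$configId,
               cur = cfg$cur, npulses = cfg$npulses, pw = cfg$pw,
               ipp = cfg$ipp, del = cfg$del,
               y_rr = eff[["rr"]], y_pr = eff[["pr"]], y_dpdt = eff[["dpdt"]],
               included = included, reason = reason)
  })
  do.call(rbind, rows)
}

#' Maximum rate of pressure rise over one cardiac cycle
#'
#' Central finite-difference derivative of a sampled left-ventricular pressure
#' trace, returned in mmHg/ms.
#'
#' @param pressure numeric vector of pressure samples (mmHg), >= 3 samples.
#' @param samplingRate sampling rate in Hz.
#' @return dPdtmax in mmHg/ms.
#' @export
dpdtmaxFromPressure <- function(pressure, samplingRate) {
  samplingRate <- assertNumber(samplingRate, "samplingRate",
                               min = .Machine$double.eps)
  p <- as.numeric(pressure)
  n <- length(p)
  if (n < 3) stop("need at least 3 pressure samples", call. = FALSE)
  dtMs <- 1000 / samplingRate
  deriv <- (p[3:n] - p[1:(n - 2)]) / (2 * dtMs)
  max(deriv)
}
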