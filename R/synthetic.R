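#' Simulate a cohort of ground-truth cardiac response functions
#'
#' Each subject carries a known, noiseless response function mapping a VNS
#' configuration to the relative change (in % of baseline) of each cardiac
#' marker: RR interval (chronotropic), PR interval (dromotropic) and dPdtmax
#' (inotropic). The functional form is
#' `amp * logistic((drive - thr) / slope) * (npulses/4)^gamma + small ipp/del terms`
#' with recruitment drive `cur * (pw/pwMax)^pwExp`, chosen as the simplest form
#' in which current dominates, pulse width comes second, the current x
#' pulse-width interaction is strong, pulse count contributes a few percent,
#' and interpulse period and delay are near-null (their linear terms account
#' for well under 2% of the output variance by construction).
#'
#' Inter-individual variability multiplies each subject's amplitudes,
#' baselines and recruitment threshold by independent log-normal factors with
#' coefficient of variation `dispersion`; with `dispersion = 0` all subjects
#' share the identical ground truth.
#'
#' @param nSubjects number of subjects (default 6).
#' @param dispersion coefficient of variation of the inter-subject log-normal
#'   factors (default 0.15).
#' @param seed integer seed; cohorts are reproducible from it.
#' @param ranges a [ParameterRanges-class]; stored for later evaluation.
#' @return an object of class `vns_cohort`: list with `subjects` (one
#'   ground-truth parameter list per subject), `dispersion`, `seed`, `ranges`.
#' @export
simulateCohort <- function(nSubjects = 6, dispersion = 0.15, seed = NULL,
                           ranges = parameterRanges()) {
  nSubjects <- assertCount(nSubjects, "nSubjects")
  dispersion <- assertNumber(dispersion, "dispersion", min = 0)
  if (!is.null(seed)) set.seed(seed)
  base <- list(
    amp = c(rr = 60, pr = 35, dpdt = -25),      # max effect, % of baseline
    thr = 0.55,                                  # recruitment threshold (drive units)
    slope = 0.11,                                # recruitment slope
    pwExp = 0.65,                                # pulse-width exponent of the drive
    npGamma = 0.6,                               # pulse-count gain exponent
    ippCoef = 0.4, delCoef = 0.4,                # residual linear terms, % units
    baseline = c(rr = 600, pr = 120, dpdt = 15)  # ms, ms, mmHg/ms
  )
  subjects <- lapply(seq_len(nSubjects), function(i) {
    s <- base
    if (dispersion > 0) {
      s$amp <- s$amp * exp(rnorm(3, 0, dispersion))
      s$baseline <- s$baseline * exp(rnorm(3, 0, dispersion))
      s$thr <- s$thr * exp(rnorm(1, 0, dispersion / 2))
    }
    s$id <- sprintf("sheep%d", i)
    s
  })
  structure(list(subjects = subjects, dispersion = dispersion, seed = seed,
                 ranges = ranges),
            class = "vns_cohort")
}

#' @export
print.vns_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, dispersion %.2f, seed %s\n",
              length(x$subjects), x$dispersion,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Noiseless ground-truth relative effect of a configuration
#'
#' Evaluates one subject's known response function at one or more
#' configurations, for one marker. The returned value is the expected relative
#' change in percent of baseline (signed: inotropic amplitudes are negative,
#' since contractility falls under vagal stimulation). The magnitude is
#' monotone non-decreasing in current and pulse width by construction.
#'
#' @param subject one element of a `vns_cohort`'s `subjects` list.
#' @param config configuration(s): named vector/list or data.frame with
#'   columns `cur, npulses, pw, ipp, del`.
#' @param marker one of `"rr"`, `"pr"`, `"dpdt"`.
#' @param ranges a [ParameterRanges-class] used to centre the residual terms.
#' @return numeric vector of relative effects (%).
#' @export
trueEffect <- function(subject, config, marker = c("rr", "pr", "dpdt"),
                       ranges = parameterRanges()) {
  marker <- match.arg(marker)
  df <- asConfigFrame(config)
  lo <- ranges@lower
  hi <- ranges@upper
  drive <- df$cur * (df$pw / hi["pw"])^subject$pwExp
  recruit <- plogis((drive - subject$thr) / subject$slope)
  gain <- (df$npulses / hi["npulses"])^subject$npGamma
  sgn <- sign(subject$amp[marker])
  resid <- sgn * (subject$ippCoef * (df$ipp - mean(c(lo["ipp"], hi["ipp"]))) /
                    (hi["ipp"] - lo["ipp"]) +
                  subject$delCoef * (df$del - mean(c(lo["del"], hi["del"]))) /
                    (hi["del"] - lo["del"]))
  unname(subject$amp[marker] * recruit * gain + resid)
}

#' Mean ground-truth response across a cohort
#'
#' Convenience wrapper averaging [trueEffect()] over the subjects of a cohort;
#' used as the oracle response in recovery checks.
#'
#' @inheritParams trueEffect
#' @param cohort a `vns_cohort`.
#' @return numeric vector of cohort-mean relative effects (%).
#' @export
cohortMeanEffect <- function(cohort, config, marker = c("rr", "pr", "dpdt")) {
  marker <- match.arg(marker)
  effs <- vapply(cohort$subjects, trueEffect, numeric(nrow(asConfigFrame(config))),
                 config = config, marker = marker, ranges = cohort$ranges)
  if (is.null(dim(effs))) mean(effs) else rowMeans(effs)
}

#' Simulate one beat-level stimulation sequence
#'
#' Generates the off-period (rest) and on-period (stimulation) beat series of
#' the three markers for one subject and one configuration. Off beats scatter
#' around the subject baseline; on beats around the baseline shifted by the
#' ground-truth effect, with independent Gaussian per-beat noise of standard
#' deviation `noiseSd` percent of baseline. The first three on beats carry
#' only half the effect, mimicking the transient that the stimulation window
#' deliberately skips. Beat counts follow the period durations and the
#' instantaneous RR interval, with floors of 10 off beats and 23 on beats so
#' the analysis windows always exist. The bradycardia flag is set when any
#' on-period RR exceeds `rrLimit`.
#'
#' @param subject one element of a `vns_cohort`'s `subjects` list.
#' @param config single configuration (named vector/list or one-row
#'   data.frame), optionally with an `id` field.
#' @param noiseSd per-beat noise SD in percent of baseline (default 2).
#' @param seed optional integer seed.
#' @param offDuration,onDuration period durations in seconds (40 and 30).
#' @param rrLimit bradycardia threshold in ms (default 1100).
#' @param adverse logical adverse-event flag to record (default FALSE).
#' @param ranges a [ParameterRanges-class].
#' @return an object of class `vns_sequence`: list with `subject`, `config`,
#'   `off` and `on` (data.frames with columns `beat, rr, pr, dpdt`),
#'   `bradycardia`, `adverse`.
#' @export
simulateSequence <- function(subject, config, noiseSd = 2, seed = NULL,
                             offDuration = 40, onDuration = 30,
                             rrLimit = 1100, adverse = FALSE,
                             ranges = parameterRanges()) {
  noiseSd <- assertNumber(noiseSd, "noiseSd", min = 0)
  if (!is.null(seed)) set.seed(seed)
  cfg <- asConfigFrame(config)[1, , drop = FALSE]
  eff <- vapply(c("rr", "pr", "dpdt"), function(m) {
    trueEffect(subject, cfg, m, ranges)
  }, numeric(1))
  bl <- subject$baseline
  nOff <- max(10L, as.integer(round(offDuration * 1000 / bl["rr"])))
  rrOn <- bl["rr"] * (1 + eff["rr"] / 100)
  nOn <- max(23L, as.integer(round(onDuration * 1000 / rrOn)))
  beatFrame <- function(n, frac) {
    out <- data.frame(beat = seq_len(n))
    for (m in c("rr", "pr", "dpdt")) {
      level <- bl[m] * (1 + frac * eff[m] / 100)
      out[[m]] <- level + rnorm(n, 0, noiseSd / 100 * bl[m])
    }
    out
  }
  off <- beatFrame(nOff, 0)
  on <- beatFrame(nOn, 1)
  # transient: first three stimulated beats at half effect
  if (nOn >= 3) {
    trans <- beatFrame(3, 0.5)
    on[1:3, c("rr", "pr", "dpdt")] <- trans[, c("rr", "pr", "dpdt")]
  }
  structure(
    list(subject = subject$id %||% "subject1",
         config = cfg,
         configId = if (!is.null(cfg$id)) cfg$id else NA_character_,
         off = off, on = on,
         bradycardia = any(on$rr > rrLimit),
         adverse = isTRUE(adverse)),
    class = "vns_sequence"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the full experiment: every configuration on every subject
#'
#' Applies the whole design to each subject of the cohort, in a
#' subject-specific random order (the design itself is generated once and
#' shared), producing one `vns_sequence` per subject x configuration.
#'
#' @param cohort a `vns_cohort`.
#' @param configs design data.frame from [rescaleDesign()].
#' @param noiseSd per-beat noise SD, percent of baseline.
#' @param seed integer seed controlling both application order and beat noise.
#' @param rrLimit bradycardia threshold in ms.
#' @return list of `vns_sequence` objects.
#' @export
simulateExperiment <- function(cohort, configs, noiseSd = 2, seed = NULL,
                               rrLimit = 1100) {
  if (!is.null(seed)) set.seed(seed)
  sequences <- list()
  for (subject in cohort$subjects) {
    order <- sample.int(nrow(configs))
    for (j in order) {
      sequences[[length(sequences) + 1L]] <-
        simulateSequence(subject, configs[j, , drop = FALSE], noiseSd = noiseSd,
                         rrLimit = rrLimit, ranges = cohort$ranges)
    }
  }
  sequences
}

#' Flatten sequences to the long beat-level table
#'
#' One row per beat, schema
#' `subject, config_id, phase (off|on), beat_index, rr_ms, pr_ms, dpdtmax`;
#' the same schema the beat-level CSV reader consumes.
#'
#' @param sequences list of `vns_sequence`.
#' @return data.frame in long format.
#' @export
sequencesToBeatTable <- function(sequences) {
  do.call(rbind, lapply(sequences, function(s) {
    phase <- function(df, ph) {
      data.frame(subject = s$subject, config_id = s$configId, phase = ph,
                 beat_index = df$beat, rr_ms = df$rr, pr_ms = df$pr,
                 dpdtmax = df$dpdt)
    }
    rbind(phase(s$off, "off"), phase(s$on, "on"))
  }))
}

#' Serialize a cohort's ground truth to JSON
#'
#' @param cohort a `vns_cohort`.
#' @param path output path.
#' @export
writeCohortJSON <- function(cohort, path) {
  jsonlite::write_json(
    list(dispersion = cohort$dispersion, seed = cohort$seed,
         subjects = cohort$subjects),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
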