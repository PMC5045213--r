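#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis with the protocol defaults:
#' 75 configurations, 6 subjects, 1000 cross-validation partitions, 10000
#' bootstrap resamples, 1100 ms bradycardia limit. `sobolN` is the base
#' Monte-Carlo sample count per input matrix; scale it up for production runs
#' and down for quick checks. All stage seeds are derived from `seed`, so two
#' runs with an identical configuration produce identical reports.
#'
#' @param seed master integer seed.
#' @param nConfigs number of design points (default 75).
#' @param nSubjects number of synthetic subjects (default 6).
#' @param dispersion inter-subject coefficient of variation (default 0.15).
#' @param noiseSd per-beat noise SD, percent of baseline (default 2).
#' @param designRestarts Latin-hypercube optimization restarts (default 1000).
#' @param cvPartitions cross-validation partitions (default 1000; 0 skips
#'   cross-validation and fits the first family on all data).
#' @param cvFamilies candidate covariance families, tie-break order.
#' @param gprRestarts optimizer starts for the no-CV fit (default 5).
#' @param cvRestarts optimizer starts per CV fit (default 2).
#' @param sobolN Sobol base sample count (default 2^14).
#' @param orders Sobol orders to estimate.
#' @param bootstrapR bootstrap resamples (default 10000).
#' @param rrLimit bradycardia threshold, ms (default 1100).
#' @param ranges a [ParameterRanges-class].
#' @param mode `"synthetic"`, `"beat-csv"` or `"effects-csv"`.
#' @param inputPath input file for the file modes.
#' @param designPath design CSV for `"beat-csv"` mode.
#' @param columnMap column mapping for `"effects-csv"` mode (see
#'   [readEffectsCSV()]).
#' @param markers cardiac markers to analyze.
#' @param gridRes selectivity-surface resolution (default 50).
#' @param topK ranked effects to list (default 5).
#' @param outDir optional directory for stage artifacts (CSV/JSON).
#' @return list of class `vns_config`.
#' @export
pipelineConfig <- function(seed = 1, nConfigs = 75, nSubjects = 6,
                           dispersion = 0.15, noiseSd = 2,
                           designRestarts = 1000, cvPartitions = 1000,
                           cvFamilies = c("exponential", "gaussian", "matern52"),
                           gprRestarts = 5, cvRestarts = 2,
                           sobolN = 2^14, orders = c("1", "2", "3", "total"),
                           bootstrapR = 10000, rrLimit = 1100,
                           ranges = parameterRanges(),
                           mode = c("synthetic", "beat-csv", "effects-csv"),
                           inputPath = NULL, designPath = NULL,
                           columnMap = NULL,
                           markers = c("rr", "pr", "dpdt"),
                           gridRes = 50, topK = 5, outDir = NULL) {
  mode <- match.arg(mode)
  cfg <- list(
    seed = assertCount(seed, "seed", min = 0L),
    nConfigs = assertCount(nConfigs, "nConfigs"),
    nSubjects = assertCount(nSubjects, "nSubjects"),
    dispersion = assertNumber(dispersion, "dispersion", min = 0),
    noiseSd = assertNumber(noiseSd, "noiseSd", min = 0),
    designRestarts = assertCount(designRestarts, "designRestarts"),
    cvPartitions = assertCount(cvPartitions, "cvPartitions", min = 0L),
    cvFamilies = match.arg(cvFamilies, GPR_FAMILIES, several.ok = TRUE),
    gprRestarts = assertCount(gprRestarts, "gprRestarts"),
    cvRestarts = assertCount(cvRestarts, "cvRestarts"),
    sobolN = assertCount(sobolN, "sobolN", min = 2L),
    orders = as.character(orders),
    bootstrapR = assertCount(bootstrapR, "bootstrapR"),
    rrLimit = assertNumber(rrLimit, "rrLimit", min = .Machine$double.eps),
    ranges = ranges, mode = mode, inputPath = inputPath,
    designPath = designPath, columnMap = columnMap,
    markers = match.arg(markers, c("rr", "pr", "dpdt"), several.ok = TRUE),
    gridRes = assertCount(gridRes, "gridRes", min = 2L),
    topK = assertCount(topK, "topK", min = 0L),
    outDir = outDir
  )
  if (mode != "synthetic" && is.null(cfg$inputPath)) {
    stop("'inputPath' is required in mode ", mode, call. = FALSE)
  }
  class(cfg) <- "vns_config"
  cfg
}

# short polynomial hash of the serialized configuration, embedded in artifacts
configHash <- function(config) {
  plain <- unclass(config)
  plain$ranges <- list(lower = config$ranges@lower, upper = config$ranges@upper)
  s <- as.character(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes design generation (or ingestion), data simulation (or reading),
#' effect quantification with exclusions, per-subject per-marker surrogate
#' fitting (with covariance-family cross-validation), Sobol sensitivity
#' estimation, bootstrap inter-subject summaries, effect ranking, paired
#' comparisons between cardiac effects, and the chronotropic/inotropic
#' selectivity metrics on the pulse-count x current plane. A subject-marker
#' whose response is degenerate (zero variance) is reported in `errors`
#' rather than aborting the run.
#'
#' @param config a `vns_config` from [pipelineConfig()].
#' @return object of class `vns_report`; see the package vignette for the
#'   component tables.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "vns_config")) {
    stop("'config' must come from pipelineConfig()", call. = FALSE)
  }
  sd0 <- config$seed
  ranges <- config$ranges
  errors <- character()

  # --- experimental design -------------------------------------------------
  if (config$mode == "beat-csv" && !is.null(config$designPath)) {
    configs <- readDesignCSV(config$designPath)
    unitDesign <- NULL
  } else {
    unitDesign <- generateLHS(config$nConfigs, length(VNS_PARAMS),
                              seed = sd0 + 1, nRestarts = config$designRestarts)
    configs <- rescaleDesign(unitDesign, ranges)
  }

  # --- data and per-configuration effects ----------------------------------
  cohort <- NULL
  if (config$mode == "synthetic") {
    cohort <- simulateCohort(config$nSubjects, config$dispersion,
                             seed = sd0 + 2, ranges = ranges)
    sequences <- simulateExperiment(cohort, configs, noiseSd = config$noiseSd,
                                    seed = sd0 + 3, rrLimit = config$rrLimit)
    effects <- applyExclusions(sequences, rrLimit = config$rrLimit)
  } else if (config$mode == "beat-csv") {
    sequences <- readBeatCSV(config$inputPath, design = configs,
                             rrLimit = config$rrLimit)
    effects <- applyExclusions(sequences, rrLimit = config$rrLimit)
  } else {
    effects <- readEffectsCSV(config$inputPath, config$columnMap)
  }
  exclusionLog <- effects[!effects$included, c("subject", "config_id", "reason")]

  # --- surrogate models ----------------------------------------------------
  subjects <- unique(effects$subject)
  markerCol <- c(rr = "y_rr", pr = "y_pr", dpdt = "y_dpdt")
  models <- list()
  modelRows <- list()
  indices <- list()
  for (s in subjects) {
    sub <- effects[effects$subject == s & effects$included, ]
    X <- as.matrix(sub[, VNS_PARAMS])
    models[[s]] <- list()
    indices[[s]] <- list()
    for (m in config$markers) {
      y <- sub[[markerCol[m]]]
      fitSeed <- sd0 + 4
      if (config$cvPartitions > 0) {
        cv <- crossValidate(X, y, families = config$cvFamilies,
                            nPartitions = config$cvPartitions,
                            nRestarts = config$cvRestarts, seed = fitSeed,
                            lower = ranges)
        model <- cv@model
        family <- cv@winningFamily
        modelRmse <- cv@rmse
      } else {
        model <- fitGPR(X, y, family = config$cvFamilies[1],
                        nRestarts = config$gprRestarts, seed = fitSeed,
                        lower = ranges)
        family <- config$cvFamilies[1]
        modelRmse <- rmse(model, X, y)
      }
      models[[s]][[m]] <- model
      modelRows[[length(modelRows) + 1L]] <- data.frame(
        subject = s, marker = m, nSequences = nrow(sub),
        family = family, rmse = modelRmse)
      si <- tryCatch(
        sobolIndices(model, n = config$sobolN, ranges = ranges,
                     seed = sd0 + 5, orders = config$orders),
        error = function(e) {
          errors <<- c(errors, sprintf("sobol/%s/%s: %s", s, m,
                                       conditionMessage(e)))
          NULL
        })
      indices[[s]][[m]] <- si
    }
  }
  modelTable <- do.call(rbind, modelRows)

  # --- bootstrap inter-subject summaries -----------------------------------
  bootRows <- list()
  for (m in config$markers) {
    for (stat in c("main", "total", "interactions")) {
      for (p in VNS_PARAMS) {
        vals <- unlist(lapply(subjects, function(s) {
          si <- indices[[s]][[m]]
          if (is.null(si)) return(NULL)
          methods::slot(si, stat)[p]
        }))
        if (!length(vals)) next
        bs <- bootstrapMeanCI(vals, R = config$bootstrapR, seed = sd0 + 6)
        bootRows[[length(bootRows) + 1L]] <- data.frame(
          marker = m, param = p, stat = stat, mean = bs$mean, sd = sd(vals),
          bootSd = bs$sd, ciLow = bs$ciLow, ciHigh = bs$ciHigh, n = length(vals))
      }
    }
  }
  bootstrapTable <- do.call(rbind, bootRows)

  # --- pooled indices and top-k ranking ------------------------------------
  pooled <- list()
  ranking <- list()
  for (m in config$markers) {
    sis <- Filter(Negate(is.null), lapply(subjects, function(s) indices[[s]][[m]]))
    if (!length(sis)) next
    pooled[[m]] <- meanIndices(sis)
    if (all(c("2", "3") %in% config$orders)) {
      ranking[[m]] <- rankEffects(pooled[[m]], k = config$topK)
    }
  }

  # --- paired comparisons between cardiac effects --------------------------
  comparisons <- NULL
  if (length(subjects) >= 2 && length(config$markers) >= 2) {
    cmpRows <- list()
    prs <- utils::combn(config$markers, 2, simplify = FALSE)
    for (pr in prs) {
      for (stat in c("main", "interactions")) {
        for (p in VNS_PARAMS) {
          v1 <- unlist(lapply(subjects, function(s) {
            si <- indices[[s]][[pr[1]]]
            if (is.null(si)) NULL else methods::slot(si, stat)[p]
          }))
          v2 <- unlist(lapply(subjects, function(s) {
            si <- indices[[s]][[pr[2]]]
            if (is.null(si)) NULL else methods::slot(si, stat)[p]
          }))
          if (length(v1) != length(v2) || length(v1) < 2) next
          w <- wilcoxonPaired(v1, v2)
          cmpRows[[length(cmpRows) + 1L]] <- data.frame(
            effect1 = pr[1], effect2 = pr[2], param = p, stat = stat,
            statistic = w$statistic, p.value = w$p.value)
        }
      }
    }
    comparisons <- do.call(rbind, cmpRows)
  }

  # --- chronotropic vs inotropic selectivity on the npulses x cur plane ----
  selectivity <- NULL
  if (all(c("rr", "dpdt") %in% config$markers)) {
    fixedSel <- c(pw = 0.1, ipp = 31.25, del = 94)
    set.seed(sd0 + 7)
    refSample <- sampleInputMatrices(2000, ranges = ranges)$A
    chronoS <- list(); inoS <- list(); chronoM <- list(); inoM <- list()
    ok <- TRUE
    for (i in seq_along(subjects)) {
      s <- subjects[i]
      mr <- models[[s]][["rr"]]
      mi <- models[[s]][["dpdt"]]
      if (is.null(mr) || is.null(mi)) { ok <- FALSE; break }
      chronoS[[i]] <- surfaceResponse(mr, c("npulses", "cur"), fixedSel,
                                      ranges, gridRes = config$gridRes)
      inoS[[i]] <- surfaceResponse(mi, c("npulses", "cur"), fixedSel,
                                   ranges, gridRes = config$gridRes)
      chronoM[[i]] <- max(abs(predict(mr, refSample)$mean))
      inoM[[i]] <- max(abs(predict(mi, refSample)$mean))
    }
    if (ok) {
      selectivity <- selectivityMetrics(chronoS, inoS, chronoM, inoM)
    }
  }

  report <- structure(
    list(config = config, configHash = configHash(config),
         unitDesign = unitDesign, design = configs, cohort = cohort,
         effects = effects, exclusionLog = exclusionLog,
         modelTable = modelTable, models = models, indices = indices,
         bootstrapTable = bootstrapTable, pooled = pooled, ranking = ranking,
         comparisons = comparisons, selectivity = selectivity,
         errors = errors),
    class = "vns_report")
  if (!is.null(config$outDir)) writeReportArtifacts(report, config$outDir)
  report
}

# average SensitivityIndices over subjects (slot-wise); interactions kept as
# the exact total - main identity
meanIndices <- function(sis) {
  avg <- function(get) rowMeans(vapply(sis, get, get(sis[[1]])))
  main <- avg(function(x) x@main)
  total <- avg(function(x) x@total)
  methods::new("SensitivityIndices",
               variance = mean(vapply(sis, function(x) x@variance, 0)),
               mean = mean(vapply(sis, function(x) x@mean, 0)),
               main = main, total = total,
               second = if (length(sis[[1]]@second)) avg(function(x) x@second)
                        else numeric(0),
               third = if (length(sis[[1]]@third)) avg(function(x) x@third)
                       else numeric(0),
               interactions = total - main,
               nSamples = sis[[1]]@nSamples,
               nEvaluations = sum(vapply(sis, function(x) x@nEvaluations, 0L)),
               orders = sis[[1]]@orders, seed = sis[[1]]@seed)
}

#' @export
print.vns_report <- function(x, ...) {
  cat("VNS parameter-sensitivity analysis report (config", x$configHash, ")\n")
  cat(sprintf("  %d configurations x %d subjects, %d sequences included, %d excluded\n",
              nrow(x$design), length(unique(x$effects$subject)),
              sum(x$effects$included), nrow(x$exclusionLog)))
  if (!is.null(x$modelTable)) {
    cat("  surrogate RMSE (% of baseline) by subject and marker:\n")
    print(x$modelTable, row.names = FALSE)
  }
  for (m in names(x$pooled)) {
    cat(sprintf("  pooled main indices, %s:\n", m))
    print(round(x$pooled[[m]]@main, 3))
  }
  if (!is.null(x$selectivity)) {
    cat(sprintf("  selectivity (npulses x cur plane): chronotropic %.1f%%, inotropic %.1f%% of max (p = %.3g)\n",
                x$selectivity$chronoPct, x$selectivity$inoPct,
                x$selectivity$p.value))
  }
  if (length(x$errors)) cat("  stage errors:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

# flat CSV/JSON stage artifacts, each embedding the config hash
writeReportArtifacts <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) {
    df$config_hash <- report$configHash
    df
  }
  writeDesignCSV(report$design, file.path(outDir, "design.csv"))
  write.csv(stamp(report$effects), file.path(outDir, "effects.csv"),
            row.names = FALSE)
  write.csv(stamp(report$modelTable), file.path(outDir, "models.csv"),
            row.names = FALSE)
  write.csv(stamp(report$bootstrapTable), file.path(outDir, "bootstrap.csv"),
            row.names = FALSE)
  idx <- lapply(report$indices, function(bySubj) {
    lapply(bySubj, function(si) {
      if (is.null(si)) return(NULL)
      list(main = as.list(si@main), total = as.list(si@total),
           second = as.list(si@second), third = as.list(si@third),
           interactions = as.list(si@interactions),
           variance = si@variance, nSamples = si@nSamples)
    })
  })
  jsonlite::write_json(list(config_hash = report$configHash, indices = idx),
                       file.path(outDir, "indices.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
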