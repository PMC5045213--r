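BEAT_CSV_COLUMNS <- c("subject", "config_id", "phase", "beat_index",
                      "rr_ms", "pr_ms", "dpdtmax")

EFFECT_CANONICAL <- c("subject", "config_id", "cur", "npulses", "pw", "ipp",
                      "del", "y_rr", "y_pr", "y_dpdt")

#' Write the beat-level long-format CSV
#'
#' @param beatTable data.frame from [sequencesToBeatTable()].
#' @param path output path.
#' @export
writeBeatCSV <- function(beatTable, path) {
  write.csv(beatTable[, BEAT_CSV_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read beat-level sequences from a long-format CSV
#'
#' Expects columns `subject, config_id, phase (off|on), beat_index, rr_ms,
#' pr_ms, dpdtmax`, one row per beat, plus an optional `adverse` flag column
#' (any true value in a sequence marks the whole sequence). Configuration
#' parameters are joined from `design` by `config_id`.
#'
#' @param path CSV path.
#' @param design design data.frame (`id` plus the five parameter columns), or
#'   `NULL` to leave parameters unset.
#' @param rrLimit bradycardia threshold used to set the sequence flag.
#' @return list of `vns_sequence` objects.
#' @export
readBeatCSV <- function(path, design = NULL, rrLimit = 1100) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(BEAT_CSV_COLUMNS, names(df))
  if (length(missing)) {
    stop("beat CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(df[, c("subject", "config_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$subject == keys$subject[i] & df$config_id == keys$config_id[i], ]
    sub <- sub[order(sub$phase, sub$beat_index), ]
    mk <- function(ph) {
      b <- sub[sub$phase == ph, ]
      data.frame(beat = b$beat_index, rr = b$rr_ms, pr = b$pr_ms, dpdt = b$dpdtmax)
    }
    cfg <- data.frame(id = keys$config_id[i], cur = NA_real_, npulses = NA_real_,
                      pw = NA_real_, ipp = NA_real_, del = NA_real_)
    if (!is.null(design)) {
      hit <- design[design$id == keys$config_id[i], , drop = FALSE]
      if (nrow(hit) == 1) cfg[, VNS_PARAMS] <- hit[, VNS_PARAMS]
    }
    on <- mk("on")
    structure(
      list(subject = keys$subject[i], config = cfg,
           configId = keys$config_id[i],
           off = mk("off"), on = on,
           bradycardia = any(on$rr > rrLimit),
           adverse = "adverse" %in% names(sub) && any(as.logical(sub$adverse))),
      class = "vns_sequence")
  })
}

#' Read a pre-computed effects table with optional column mapping
#'
#' Ingests per-configuration relative effects from a CSV whose column names
#' may differ from the canonical schema (`subject, config_id, cur, npulses,
#' pw, ipp, del, y_rr, y_pr, y_dpdt`). `columnMap` maps source names to
#' canonical names, either as a named character vector/list
#' (`c(sheep = "subject", ...)`) or a path to a JSON object with the same
#' shape.
#'
#' @param path CSV path.
#' @param columnMap optional source-to-canonical column mapping.
#' @return data.frame in the canonical schema, with `included` defaulting to
#'   `TRUE` and `reason` to `""` when absent from the file.
#' @export
readEffectsCSV <- function(path, columnMap = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    if (is.character(columnMap) && length(columnMap) == 1 && file.exists(columnMap)) {
      columnMap <- jsonlite::read_json(columnMap, simplifyVector = TRUE)
    }
    columnMap <- unlist(columnMap)
    hit <- names(columnMap) %in% names(df)
    names(df)[match(names(columnMap)[hit], names(df))] <- unname(columnMap[hit])
  }
  missing <- setdiff(EFFECT_CANONICAL, names(df))
  if (length(missing)) {
    stop("effects table is missing column(s) after mapping: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"included" %in% names(df)) df$included <- TRUE
  if (!"reason" %in% names(df)) df$reason <- ""
  df[, c(EFFECT_CANONICAL, "included", "reason")]
}

#' Write the per-configuration effects CSV
#'
#' @param effects data.frame from [applyExclusions()] (or the same schema).
#' @param path output path.
#' @export
writeEffectsCSV <- function(effects, path) {
  write.csv(effects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a pipeline input file
#'
#' Schema check for the two file input modes: `"beat-csv"` (long beat-level
#' table) or `"effects-csv"` (per-configuration effects). Reports missing
#' columns, non-positive marker values, off periods shorter than the 10-beat
#' baseline window and on periods shorter than the 23-beat stimulation window.
#'
#' @param path input file path.
#' @param mode `"beat-csv"` or `"effects-csv"`.
#' @param columnMap optional mapping for effects files (see [readEffectsCSV()]).
#' @return list with `ok` (logical), `violations` (character vector) and
#'   `warnings` (character vector).
#' @export
validateInputs <- function(path, mode = c("beat-csv", "effects-csv"),
                           columnMap = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("cannot read input file: ", path, call. = FALSE)
  violations <- character()
  warns <- character()
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (mode == "beat-csv") {
    missing <- setdiff(BEAT_CSV_COLUMNS, names(df))
    if (length(missing)) {
      violations <- c(violations,
                      paste0("missing column: ", missing))
    } else {
      for (m in c("rr_ms", "pr_ms", "dpdtmax")) {
        bad <- sum(!is.finite(df[[m]]) | df[[m]] <= 0)
        if (bad > 0) {
          violations <- c(violations,
                          sprintf("%d non-positive or non-finite values in %s", bad, m))
        }
      }
      counts <- stats::aggregate(beat_index ~ subject + config_id + phase,
                                 df, length)
      short <- counts[counts$phase == "off" & counts$beat_index < 10, ]
      for (i in seq_len(nrow(short))) {
        warns <- c(warns, sprintf(
          "insufficient baseline: %s/%s off period has %d beats (10-beat window required)",
          short$subject[i], short$config_id[i], short$beat_index[i]))
      }
      shortOn <- counts[counts$phase == "on" & counts$beat_index < 23, ]
      for (i in seq_len(nrow(shortOn))) {
        warns <- c(warns, sprintf(
          "%s/%s on period has %d beats (< 23); stimulation window will be truncated",
          shortOn$subject[i], shortOn$config_id[i], shortOn$beat_index[i]))
      }
    }
  } else {
    eff <- tryCatch(readEffectsCSV(path, columnMap), error = function(e) e)
    if (inherits(eff, "error")) {
      violations <- c(violations, conditionMessage(eff))
    } else {
      for (m in c("y_rr", "y_pr", "y_dpdt")) {
        bad <- sum(!is.finite(eff[[m]]) & eff$included)
        if (bad > 0) {
          violations <- c(violations,
                          sprintf("%d non-finite included values in %s", bad, m))
        }
      }
    }
  }
  list(ok = length(violations) == 0, violations = violations, warnings = warns)
}
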