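#' Read a raw gaze log
#'
#' Parses a delimited gaze log (one row per sample) into a raw-sample table.
#' The delimiter is auto-detected among comma, tab and semicolon; a header
#' row is required. Missing coordinate cells become `NA`, never zeros. Rows
#' whose timestamp cannot be parsed are dropped with a message reporting the
#' count.
#'
#' @param path Path to the log file.
#' @param column_map Named list mapping the mandatory roles `time`, `x_left`,
#'   `y_left`, `x_right`, `y_right`, `validity_left`, `validity_right` (and
#'   optionally `marker`) to column names in the file. Defaults to those
#'   role names themselves, except `time`, which defaults to `time_us`.
#' @param time_unit Unit of the time column: `"us"` (default), `"ms"` or
#'   `"s"`; converted to integer-like microseconds on read.
#' @return `data.frame` of samples in file order with canonical column
#'   names `time_us`, `x_left`, ..., `validity_right`, `marker`.
#' @export
read_gaze_log <- function(path,
                          column_map = NULL,
                          time_unit = c("us", "ms", "s")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("gaze log not found: ", path, call. = FALSE)
  roles <- c("time", "x_left", "y_left", "x_right", "y_right",
             "validity_left", "validity_right")
  map <- stats::setNames(as.list(roles), roles)
  map$time <- "time_us"
  map$marker <- "marker"
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  dat <- data.table::fread(path, sep = "auto", header = TRUE,
                           data.table = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(unlist(map[roles]), names(dat))
  if (length(missing_cols))
    stop("gaze log lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tm <- suppressWarnings(as.numeric(dat[[map$time]]))
  bad <- is.na(tm)
  if (any(bad)) {
    message(sum(bad), " row(s) with unparseable timestamps dropped")
    dat <- dat[!bad, , drop = FALSE]
    tm <- tm[!bad]
  }
  scale <- switch(time_unit, us = 1, ms = 1e3, s = 1e6)
  out <- data.frame(
    time_us = tm * scale,
    x_left = suppressWarnings(as.numeric(dat[[map$x_left]])),
    y_left = suppressWarnings(as.numeric(dat[[map$y_left]])),
    x_right = suppressWarnings(as.numeric(dat[[map$x_right]])),
    y_right = suppressWarnings(as.numeric(dat[[map$y_right]])),
    validity_left = suppressWarnings(as.integer(dat[[map$validity_left]])),
    validity_right = suppressWarnings(as.integer(dat[[map$validity_right]])),
    marker = if (map$marker %in% names(dat)) as.character(dat[[map$marker]])
             else NA_character_,
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 1 && any(diff(out$time_us) <= 0)) {
    first_bad <- which(diff(out$time_us) <= 0)[1] + 1L
    stop("timestamps not strictly increasing at row ", first_bad,
         call. = FALSE)
  }
  out
}

#' Segment a raw gaze log into trial traces
#'
#' Cuts the continuous sample stream into one [gaze_trace] per row of the
#' trial table. Each trace spans
#' `[first_onset, second_onset + max(srt_max_ms, min_second_ms)]`: the SRT
#' scan needs data to `srt_max_ms` and the duration check needs evidence
#' that the second stimulus was recorded for `min_second_ms`; data beyond
#' both plays no role in any downstream check. Trials whose
#' second-stimulus marker never occurs
#' are skipped with a warning. Eye combination (see [combine_eyes]) is
#' applied during segmentation so every trace carries the combined raw
#' stream.
#'
#' @param samples Raw sample table from [read_gaze_log].
#' @param trial_table `data.frame` with columns `subject_id`, `trial_number`,
#'   `condition`, `target_side`, and either absolute onsets
#'   (`first_onset_us`, `second_onset_us`) or marker values (`first_marker`,
#'   `second_marker`) resolved to the time of their first occurrence.
#' @param params An [srt_params] object (window length, valid codes, rate).
#' @return List of `gaze_trace` objects (possibly with empty sample tables;
#'   downstream checks reject those).
#' @export
segment_trials <- function(samples, trial_table, params = srt_params()) {
  traces <- vector("list", nrow(trial_table))
  keep <- logical(nrow(trial_table))
  for (i in seq_len(nrow(trial_table))) {
    row <- trial_table[i, ]
    on1 <- resolve_onset(row, samples, "first")
    on2 <- resolve_onset(row, samples, "second")
    if (is.na(on1) || is.na(on2)) {
      warning(sprintf("trial %s/%s unsegmentable: missing onset/marker; skipped",
                      row$subject_id, row$trial_number), call. = FALSE)
      next
    }
    win_end <- on2 + max(params$srt_max_ms, params$min_second_ms) * 1000
    sel <- samples$time_us >= on1 & samples$time_us <= win_end
    combined <- combine_eyes(samples[sel, , drop = FALSE], params$valid_codes)
    traces[[i]] <- gaze_trace(row$subject_id, row$trial_number, row$condition,
                              row$target_side, on1, on2, combined,
                              rate_hz = params$rate_hz)
    keep[i] <- TRUE
  }
  traces[keep]
}

# Resolve an onset from either an absolute column or a marker column.
resolve_onset <- function(row, samples, which = c("first", "second")) {
  which <- match.arg(which)
  abs_col <- paste0(which, "_onset_us")
  mark_col <- paste0(which, "_marker")
  if (abs_col %in% names(row) && !is.na(row[[abs_col]]))
    return(as.numeric(row[[abs_col]]))
  if (mark_col %in% names(row) && !is.na(row[[mark_col]])) {
    hit <- which(samples$marker == row[[mark_col]])
    if (length(hit)) return(samples$time_us[hit[1]])
  }
  NA_real_
}

#' Write trial-by-trial results
#'
#' One row per analyzed trial: identifiers, the verification outcome, the
#' SRT (empty cell when rejected), and the key intermediate quantities
#' (longest interpolated gap, fixation proportion). Column order is fixed:
#' `subject_id, trial_number, condition, target_side, status, srt_ms,
#' longest_gap_ms, fixation_prop`.
#'
#' @param results `data.frame` of trial results (rows from [verify_trial]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_results <- function(results, path) {
  cols <- c("subject_id", "trial_number", "condition", "target_side",
            "status", "srt_ms", "longest_gap_ms", "fixation_prop")
  if (nrow(results) == 0) {
    results <- stats::setNames(
      data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  }
  out <- results[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 3)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the per-participant condition summary
#'
#' One row per participant; each condition contributes a group of columns
#' (`<condition>_n_valid`, `_n_no_shift`, `_n_rejected`, `_mean_srt_ms`,
#' `_srt_index`, `_insufficient`), so the file reads directly into standard
#' statistics packages. Subjects with no valid shifts in a condition get a
#' zero count and an empty mean-SRT cell.
#'
#' @param summaries Long-format summary table from [summarize_conditions].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path) {
  if (nrow(summaries) &&
      anyDuplicated(summaries[, c("subject_id", "condition")]))
    stop("duplicate subject x condition rows in summary", call. = FALSE)
  fields <- c("n_valid_shift", "n_no_shift", "n_rejected",
              "mean_srt_ms", "srt_index", "insufficient")
  subjects <- unique(summaries$subject_id)
  conditions <- unique(summaries$condition)
  wide <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (cond in conditions) {
    sub <- summaries[summaries$condition == cond, , drop = FALSE]
    idx <- match(subjects, sub$subject_id)
    for (f in fields) {
      v <- sub[[f]][idx]
      if (is.numeric(v)) v <- round(v, 3)
      wide[[paste(cond, f, sep = "_")]] <- v
    }
  }
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  invisible(path)
}
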