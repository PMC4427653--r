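#' Excerpt the segment used for quality metrics
#'
#' Quality metrics are computed on the samples from trial start up to the
#' first saccadic eye movement when one was detected, and otherwise on the
#' first 2000 ms of the trial (clipped to the trial's extent).
#'
#' @param trace A [gaze_trace].
#' @param result The trial's one-row result.
#' @return `data.frame` subset of `trace$samples`.
#' @export
excerpt_quality_segment <- function(trace, result) {
  s <- trace$samples
  end_us <- if (identical(result$status, "valid_shift"))
    trace$second_onset_us + result$srt_ms * 1000
  else trace$first_onset_us + 2000 * 1000
  s[s$time_us >= trace$first_onset_us & s$time_us <= end_us, , drop = FALSE]
}

#' Precision of a gaze segment (inter-sample RMS)
#'
#' Root-mean-square of the Euclidean distances between consecutive valid
#' raw samples (consecutive in the recording; pairs spanning a gap are
#' excluded). Smaller is more precise. For isotropic white jitter of
#' standard deviation sigma per axis, the large-sample RMS is 2*sigma.
#'
#' @param segment Sample `data.frame` with `x_raw`, `y_raw`, `valid_raw`.
#' @param display_span_deg Optional display span; when given, the value is
#'   also returned in degrees via the linear mapping
#'   [norm_to_degrees].
#' @return RMS in normalized units (attribute `degrees` when a span is
#'   given), or `NA_real_` with fewer than one usable pair.
#' @export
precision_rms <- function(segment, display_span_deg = NULL) {
  v <- segment$valid_raw
  n <- nrow(segment)
  if (n < 2) return(NA_real_)
  pair <- v[-n] & v[-1]
  if (!any(pair)) return(NA_real_)
  dx <- diff(segment$x_raw)[pair]
  dy <- diff(segment$y_raw)[pair]
  rms <- sqrt(mean(dx^2 + dy^2))
  if (!is.null(display_span_deg))
    attr(rms, "degrees") <- norm_to_degrees(rms, display_span_deg)
  rms
}

#' Robustness of a gaze segment (proportion of unavailable data)
#'
#' Fraction of samples that are not raw-valid; 0 means uninterrupted
#' tracking, 1 fully missing. Depends only on validity flags, never on
#' coordinate values.
#'
#' @param segment Sample `data.frame` with `valid_raw`.
#' @return Fraction in `[0, 1]`.
#' @export
robustness <- function(segment) {
  if (nrow(segment) == 0) stop("empty segment", call. = FALSE)
  mean(!segment$valid_raw)
}

#' Durations of maximal usable data segments
#'
#' Run lengths of consecutive raw-valid samples converted to milliseconds
#' at the nominal rate (one period per sample).
#'
#' @param trace A [gaze_trace] (or any object with `samples$valid_raw` and
#'   `rate_hz`).
#' @return Numeric vector of durations in ms (empty when no valid sample).
#' @export
segment_durations <- function(trace) {
  v <- trace$samples$valid_raw
  if (!length(v) || !any(v)) return(numeric())
  r <- rle(v)
  r$lengths[r$values] * 1000 / trace$rate_hz
}

#' Full per-trial quality report
#'
#' @param trace A [gaze_trace].
#' @param result The trial's result row (selects the excerpt window).
#' @param params An [srt_params] object (display span for degrees).
#' @return One-row `data.frame`: identifiers, `precision_rms`,
#'   `precision_deg`, `robustness_missing_prop`, `n_segments`,
#'   `median_segment_ms`.
#' @export
quality_report <- function(trace, result, params = srt_params()) {
  seg <- excerpt_quality_segment(trace, result)
  durs <- segment_durations(trace)
  prec <- if (nrow(seg)) precision_rms(seg) else NA_real_
  data.frame(
    subject_id = trace$subject_id,
    trial_number = trace$trial_number,
    condition = trace$condition,
    precision_rms = as.numeric(prec),
    precision_deg = norm_to_degrees(as.numeric(prec), params$display_span_deg),
    robustness_missing_prop = if (nrow(seg)) robustness(seg) else NA_real_,
    n_segments = length(durs),
    median_segment_ms = if (length(durs)) stats::median(durs) else NA_real_,
    stringsAsFactors = FALSE
  )
}

# Pearson chi-square on a 2x2 table; degenerate margins yield NA + reason.
pearson_chisq <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_,
                reason = "degenerate table (empty row or column)"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, reason = NA_character_)
}

#' Median-split quality sensitivity experiment
#'
#' Asks whether large SRT errors (detected vs. ground-truth latency
#' differing by more than `error_ms`) concentrate in low-quality trials.
#' Trials are split at the median of each quality metric (precision RMS and
#' missing-data proportion; values at the median go to the low-quality
#' group), and a Pearson chi-square test is run on the 2x2 table quality
#' half x large/small error.
#'
#' Two analysis modes are compared on identical traces. `"full"` runs the
#' complete pipeline: eye combination, interpolation, median filtering,
#' detection on the preprocessed stream, and all four verification checks.
#' `"typical"` emulates a conventional analysis: detection on the raw
#' stream with no interpolation, no filtering, no checks, and a central AOI
#' narrowed by reducing the stimulus-side margin from 2.7 to 1 degree
#' (applied symmetrically as `1.7 / display_span_deg` added to the edge
#' threshold).
#'
#' @param traces List of [gaze_trace] objects (raw, eye-combined).
#' @param truth `data.frame` with `subject_id`, `trial_number`,
#'   `true_srt_ms` (`NA` plus `no_shift = TRUE` for no-shift ground truth).
#' @param params An [srt_params] object.
#' @param mode `"full"` or `"typical"`.
#' @param error_ms Large-error threshold in ms (default 100).
#' @param margin_reduction_deg AOI narrowing for typical mode, degrees.
#' @return Object of class `quality_split` : list with `per_trial`
#'   (`data.frame`), `tables` (named list of 2x2 tables), and `stats`
#'   (`data.frame`: metric, mode, cell counts, chi-square, p, reason).
#' @export
quality_split_experiment <- function(traces, truth, params = srt_params(),
                                     mode = c("full", "typical"),
                                     error_ms = 100,
                                     margin_reduction_deg = 1.7) {
  mode <- match.arg(mode)
  det_params <- params
  if (mode == "typical") {
    det_params$edge_threshold <- params$edge_threshold +
      margin_reduction_deg / params$display_span_deg
  }
  rows <- lapply(traces, function(tr) {
    if (mode == "full") {
      pp <- preprocess_trace(tr, params)
      det <- detect_srt(pp$trace, params)
      res <- verify_trial(pp$trace, pp$records, det, params)
      qtr <- pp$trace
    } else {
      res <- detect_srt(tr, det_params, stream = "raw")
      qtr <- tr
    }
    q <- quality_report(qtr, res, params)
    cbind(res[, c("subject_id", "trial_number", "status", "srt_ms")],
          q[, c("precision_rms", "robustness_missing_prop")])
  })
  per_trial <- do.call(rbind, rows)
  key_t <- paste(truth$subject_id, truth$trial_number)
  idx <- match(paste(per_trial$subject_id, per_trial$trial_number), key_t)
  ref <- truth$true_srt_ms[idx]
  ref[!is.na(truth$no_shift[idx]) & truth$no_shift[idx]] <- params$srt_max_ms
  per_trial$reference_ms <- ref
  scorable <- per_trial$status %in% c("valid_shift", "no_shift") &
    !is.na(per_trial$reference_ms)
  per_trial$error_ms <- ifelse(scorable,
                               abs(per_trial$srt_ms - per_trial$reference_ms),
                               NA_real_)
  per_trial$large_error <- per_trial$error_ms > error_ms
  sc <- per_trial[scorable & !is.na(per_trial$precision_rms), , drop = FALSE]
  split_one <- function(metric) {
    v <- sc[[metric]]
    med <- stats::median(v)
    low_quality <- v >= med   # ties join the low-quality group
    tab <- table(factor(ifelse(low_quality, "low", "high"),
                        levels = c("high", "low")),
                 factor(ifelse(sc$large_error, "large", "small"),
                        levels = c("large", "small")))
    cs <- pearson_chisq(tab)
    list(table = tab,
         stats = data.frame(metric = metric, mode = mode,
                            n = nrow(sc),
                            high_large = tab["high", "large"],
                            high_small = tab["high", "small"],
                            low_large = tab["low", "large"],
                            low_small = tab["low", "small"],
                            chi_sq = cs$statistic, p_value = cs$p_value,
                            reason = cs$reason,
                            stringsAsFactors = FALSE))
  }
  prec <- split_one("precision_rms")
  rob <- split_one("robustness_missing_prop")
  structure(list(
    per_trial = per_trial,
    tables = list(precision = prec$table, robustness = rob$table),
    stats = rbind(prec$stats, rob$stats)
  ), class = "quality_split")
}

#' @export
print.quality_split <- function(x, ...) {
  cat("Quality median-split experiment (", x$stats$mode[1], " mode, n = ",
      x$stats$n[1], " scorable trials)\n", sep = "")
  print(x$stats[, c("metric", "high_large", "high_small", "low_large",
                    "low_small", "chi_sq", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Write quality-split experiment results to CSV
#'
#' @param experiments List of `quality_split` objects (e.g., one per mode).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quality_experiment <- function(experiments, path) {
  stats <- do.call(rbind, lapply(experiments, `[[`, "stats"))
  utils::write.csv(stats, path, row.names = FALSE, na = "")
  invisible(path)
}
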