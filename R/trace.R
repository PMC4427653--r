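#' Construct a gaze trace for one trial
#'
#' A gaze trace holds one trial's combined-gaze sample sequence together with
#' its stimulus-onset metadata. The sample table carries both the raw
#' combined stream (`x_raw`, `y_raw`, `valid_raw`) and, after preprocessing,
#' the interpolated and filtered stream (`x`, `y`, `interpolated`). The raw
#' stream is kept because the border-violation check and the quality metrics
#' must see what the tracker actually reported.
#'
#' @param subject_id Subject identifier (character).
#' @param trial_number Trial number (integer >= 1).
#' @param condition Condition label.
#' @param target_side `"left"` or `"right"`: side of the lateral stimulus.
#' @param first_onset_us Onset of the first (central) stimulus, microseconds.
#' @param second_onset_us Onset of the second (lateral) stimulus, microseconds.
#' @param samples `data.frame` with columns `time_us`, `x_raw`, `y_raw`,
#'   `valid_raw`; columns `x`, `y`, `interpolated` are added if absent.
#' @param rate_hz Nominal sampling rate.
#' @return An object of class `gaze_trace`.
#' @export
gaze_trace <- function(subject_id, trial_number, condition, target_side,
                       first_onset_us, second_onset_us, samples,
                       rate_hz = 300) {
  stopifnot_side(target_side)
  if (second_onset_us <= first_onset_us)
    stop("second_onset_us must exceed first_onset_us", call. = FALSE)
  need <- c("time_us", "x_raw", "y_raw", "valid_raw")
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(samples) > 1 && any(diff(samples$time_us) <= 0))
    stop("sample timestamps must be strictly increasing", call. = FALSE)
  if (!"x" %in% names(samples)) {
    samples$x <- ifelse(samples$valid_raw, samples$x_raw, NA_real_)
    samples$y <- ifelse(samples$valid_raw, samples$y_raw, NA_real_)
  }
  if (!"interpolated" %in% names(samples))
    samples$interpolated <- rep(FALSE, nrow(samples))
  structure(list(
    subject_id = as.character(subject_id),
    trial_number = as.integer(trial_number),
    condition = as.character(condition),
    target_side = target_side,
    first_onset_us = as.numeric(first_onset_us),
    second_onset_us = as.numeric(second_onset_us),
    rate_hz = rate_hz,
    samples = samples
  ), class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("gaze_trace: subject %s trial %d (%s, target %s)\n",
              x$subject_id, x$trial_number, x$condition, x$target_side))
  cat(sprintf("  %d samples at %g Hz, onsets %.1f / %.1f ms, %.1f%% raw-valid\n",
              nrow(x$samples), x$rate_hz,
              x$first_onset_us / 1000, x$second_onset_us / 1000,
              if (nrow(x$samples)) 100 * mean(x$samples$valid_raw) else NA_real_))
  invisible(x)
}

#' Combine the two eyes into one gaze stream
#'
#' Per sample: if both eyes carry an accepted validity code and finite
#' coordinates, the combined point is the arithmetic mean of the two eyes; if
#' exactly one qualifies, that eye is used; if neither, the sample is invalid
#' and its coordinates missing. Total function, no errors.
#'
#' @param raw `data.frame` of raw samples with columns `time_us`, `x_left`,
#'   `y_left`, `x_right`, `y_right`, `validity_left`, `validity_right`.
#' @param valid_codes Validity codes accepted as reliable (default `c(0, 1)`).
#' @return `data.frame` with columns `time_us`, `x_raw`, `y_raw`, `valid_raw`.
#' @examples
#' raw <- data.frame(time_us = 0, x_left = 0.40, y_left = 0.50,
#'                   x_right = 0.44, y_right = 0.50,
#'                   validity_left = 0, validity_right = 0)
#' combine_eyes(raw)$x_raw   # 0.42
#' @export
combine_eyes <- function(raw, valid_codes = c(0L, 1L)) {
  ok_l <- raw$validity_left %in% valid_codes &
    is.finite(raw$x_left) & is.finite(raw$y_left)
  ok_r <- raw$validity_right %in% valid_codes &
    is.finite(raw$x_right) & is.finite(raw$y_right)
  x <- y <- rep(NA_real_, nrow(raw))
  both <- ok_l & ok_r
  x[both] <- (raw$x_left[both] + raw$x_right[both]) / 2
  y[both] <- (raw$y_left[both] + raw$y_right[both]) / 2
  lonly <- ok_l & !ok_r
  x[lonly] <- raw$x_left[lonly]; y[lonly] <- raw$y_left[lonly]
  ronly <- ok_r & !ok_l
  x[ronly] <- raw$x_right[ronly]; y[ronly] <- raw$y_right[ronly]
  data.frame(time_us = raw$time_us, x_raw = x, y_raw = y,
             valid_raw = ok_l | ok_r)
}

# Internal helper: build a one-row trial result data.frame.
trial_result <- function(trace, status, srt_ms = NA_real_,
                         longest_gap_ms = NA_real_,
                         fixation_prop = NA_real_) {
  data.frame(
    subject_id = trace$subject_id,
    trial_number = trace$trial_number,
    condition = trace$condition,
    target_side = trace$target_side,
    status = status,
    srt_ms = srt_ms,
    longest_gap_ms = longest_gap_ms,
    fixation_prop = fixation_prop,
    stringsAsFactors = FALSE
  )
}

# Status vocabulary shared across modules.
SRT_STATUSES <- c("valid_shift", "no_shift",
                  "rejected_duration", "rejected_interpolation",
                  "rejected_border", "rejected_fixation",
                  "rejected_anticipatory", "rejected_wrong_direction")
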