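#' Detect the saccadic reaction time of one trial
#'
#' The SRT is the latency from second-stimulus onset to the last sample
#' inside the central AOI preceding the gaze's transition toward the lateral
#' target. Samples with timestamps in
#' `[second_onset, second_onset + srt_max_ms]` are scanned for the first
#' departure from the central band; the exit side must match the trial's
#' target side. The scan starts at onset (not at `srt_min_ms`) so that
#' anticipatory shifts are detected and rejected rather than silently
#' skipped.
#'
#' Outcomes: `valid_shift` with `srt_ms` in `[srt_min_ms, srt_max_ms]`;
#' `no_shift` with `srt_ms = srt_max_ms` when gaze never leaves the AOI in
#' the window; `rejected_anticipatory` when the detected latency falls below
#' `srt_min_ms` (or the gaze was already outside with no prior in-AOI
#' sample); `rejected_wrong_direction` when the first departure exits on the
#' non-target side; `rejected_duration` when the window holds no samples
#' (the duration check would reject such a trial anyway).
#'
#' Only x participates in detection; in vertically aligned two-stimulus
#' paradigms y stays roughly constant and is kept for quality metrics only.
#'
#' @param trace A preprocessed [gaze_trace] (interpolated and filtered); set
#'   `stream = "raw"` to run detection on the raw combined stream instead
#'   (used by the "typical approach" ablation).
#' @param params An [srt_params] object.
#' @param stream Which coordinate stream to scan: `"processed"` (default)
#'   or `"raw"`.
#' @return One-row `data.frame` trial result with `status` and `srt_ms`
#'   (verification checks are applied separately by [verify_trial]).
#' @export
detect_srt <- function(trace, params = srt_params(),
                       stream = c("processed", "raw")) {
  stream <- match.arg(stream)
  s <- trace$samples
  xs <- if (stream == "processed") s$x else ifelse(s$valid_raw, s$x_raw, NA_real_)
  on <- trace$second_onset_us
  win <- which(s$time_us >= on & s$time_us <= on + params$srt_max_ms * 1000)
  if (!length(win)) return(trial_result(trace, "rejected_duration"))
  inside <- in_central_aoi(xs, params$edge_threshold)
  out_idx <- win[!is.na(inside[win]) & !inside[win]]
  if (!length(out_idx)) {
    return(trial_result(trace, "no_shift", srt_ms = params$srt_max_ms))
  }
  dep <- out_idx[1]
  side <- if (xs[dep] > 1 - params$edge_threshold) "right" else "left"
  prior <- seq_len(dep - 1L)
  prior_in <- prior[!is.na(inside[prior]) & inside[prior]]
  if (side != trace$target_side)
    return(trial_result(trace, "rejected_wrong_direction"))
  if (!length(prior_in))
    return(trial_result(trace, "rejected_anticipatory"))
  srt <- (s$time_us[max(prior_in)] - on) / 1000
  if (srt < params$srt_min_ms)
    return(trial_result(trace, "rejected_anticipatory"))
  trial_result(trace, "valid_shift", srt_ms = srt)
}
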