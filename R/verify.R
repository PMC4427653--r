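#' Stimulus-duration check
#'
#' Fails when the span of recorded samples during the first-stimulus phase
#' `[first_onset, second_onset)` falls outside
#' `[min_first_ms, max_first_ms]`, or when the second-stimulus phase
#' (from `second_onset` onward within the trace) covers less than
#' `min_second_ms`. The span counts one nominal sample period per phase
#' (last minus first timestamp plus one period), so a complete 300-sample
#' phase at 300 Hz measures exactly 1000 ms. An empty trace fails.
#'
#' @param trace A [gaze_trace].
#' @param params An [srt_params] object.
#' @return List with `pass` (logical) and `first_ms` / `second_ms` spans.
#' @export
check_durations <- function(trace, params = srt_params()) {
  s <- trace$samples
  period_ms <- 1000 / trace$rate_hz
  span <- function(t) if (length(t)) (max(t) - min(t)) / 1000 + period_ms else 0
  t1 <- s$time_us[s$time_us >= trace$first_onset_us &
                    s$time_us < trace$second_onset_us]
  t2 <- s$time_us[s$time_us >= trace$second_onset_us]
  first_ms <- span(t1); second_ms <- span(t2)
  pass <- first_ms >= params$min_first_ms && first_ms <= params$max_first_ms &&
    second_ms >= params$min_second_ms
  list(pass = pass, first_ms = first_ms, second_ms = second_ms)
}

#' Interpolation-cap check
#'
#' Fails when any interpolated segment overlapping the analysis period
#' (`first_onset` to `second_onset + srt_max_ms`) exceeds `max_gap_ms`.
#' Gaps lying entirely outside the period are ignored.
#'
#' @param records Interpolation records from [interpolate_gaps].
#' @param trace The trace the records belong to (supplies the window).
#' @param params An [srt_params] object.
#' @return List with `pass` and `longest_gap_ms` (0 when no overlapping gap).
#' @export
check_interpolation <- function(records, trace, params = srt_params()) {
  win <- c(trace$first_onset_us,
           trace$second_onset_us + params$srt_max_ms * 1000)
  if (nrow(records) == 0) return(list(pass = TRUE, longest_gap_ms = 0))
  ov <- records$end_time_us >= win[1] & records$start_time_us <= win[2]
  longest <- if (any(ov)) max(records$duration_ms[ov]) else 0
  list(pass = longest <= params$max_gap_ms, longest_gap_ms = longest)
}

#' Border-violation check
#'
#' Detects AOI transitions hidden inside interpolated segments: for each
#' filled gap, the AOI region (left / central / right) of the last valid raw
#' sample before the gap is compared with that of the first valid raw sample
#' after it. If the region changes, a gaze shift took place during missing
#' data and its time is unknowable, so the trial fails. The comparison uses
#' raw (pre-interpolation) samples; interpolated values cannot, by
#' construction, reveal a shift. A gap at the trace end with no trailing
#' valid sample cannot violate and is skipped.
#'
#' @param trace A [gaze_trace] with raw validity preserved.
#' @param records Interpolation records from [interpolate_gaps].
#' @param params An [srt_params] object (AOI threshold).
#' @return List with `pass` and `violating_gap` (index into `records`, or
#'   `NA`).
#' @export
check_border_violation <- function(trace, records, params = srt_params()) {
  s <- trace$samples
  vidx <- which(s$valid_raw)
  for (g in seq_len(nrow(records))) {
    before <- vidx[vidx < records$start_index[g]]
    after <- vidx[vidx > records$end_index[g]]
    if (!length(before) || !length(after)) next
    r1 <- aoi_region(s$x_raw[max(before)], params$edge_threshold)
    r2 <- aoi_region(s$x_raw[min(after)], params$edge_threshold)
    if (!identical(r1, r2))
      return(list(pass = FALSE, violating_gap = g))
  }
  list(pass = TRUE, violating_gap = NA_integer_)
}

#' Minimum-fixation check
#'
#' Computes the proportion of samples inside the central AOI during the
#' first-stimulus presentation window `[first_onset, second_onset)`,
#' counting interpolated samples as available, over all samples in that
#' window. Fails when the proportion falls below `min_fixation_prop`
#' (inclusive bound: exactly the threshold passes) or when the window holds
#' no samples.
#'
#' @param trace A preprocessed [gaze_trace].
#' @param params An [srt_params] object.
#' @return List with `pass` and `fixation_prop`.
#' @export
check_min_fixation <- function(trace, params = srt_params()) {
  s <- trace$samples
  win <- s$time_us >= trace$first_onset_us & s$time_us < trace$second_onset_us
  n <- sum(win)
  if (n == 0) return(list(pass = FALSE, fixation_prop = NA_real_))
  inside <- in_central_aoi(s$x[win], params$edge_threshold)
  prop <- sum(inside, na.rm = TRUE) / n
  list(pass = prop >= params$min_fixation_prop, fixation_prop = prop)
}

#' Apply the post-analysis verification checks to a detection
#'
#' Runs the four checks in fixed order — durations, interpolation cap,
#' border violation, minimum fixation — so every rejected trial reports
#' exactly one (the first) reason; on first failure the status is set to
#' the corresponding `rejected_*` code and the SRT cleared. If all checks
#' pass, the detection's own status (`valid_shift`, `no_shift`, or a
#' detection-stage rejection) stands. The returned result always carries
#' `longest_gap_ms` and `fixation_prop` for reporting. Idempotent.
#'
#' @param trace A preprocessed [gaze_trace].
#' @param records Interpolation records from [interpolate_gaps].
#' @param detection One-row result from [detect_srt].
#' @param params An [srt_params] object.
#' @return One-row trial-result `data.frame`.
#' @export
verify_trial <- function(trace, records, detection, params = srt_params()) {
  dur <- check_durations(trace, params)
  gap <- check_interpolation(records, trace, params)
  bor <- check_border_violation(trace, records, params)
  fix <- check_min_fixation(trace, params)
  res <- detection
  res$longest_gap_ms <- gap$longest_gap_ms
  res$fixation_prop <- fix$fixation_prop
  fail_status <- if (!dur$pass) "rejected_duration"
    else if (!gap$pass) "rejected_interpolation"
    else if (!bor$pass) "rejected_border"
    else if (!fix$pass) "rejected_fixation"
    else NA_character_
  if (!is.na(fail_status)) {
    res$status <- fail_status
    res$srt_ms <- NA_real_
  }
  res
}
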