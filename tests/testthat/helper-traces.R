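# Trace builders and independent brute-force oracles shared across tests.

# 300-Hz grid timestamps in integer-rounded microseconds.
grid_us <- function(n, rate_hz = 300) round((seq_len(n) - 1) * 1e6 / rate_hz)

# Build a gaze_trace directly from a combined x vector (y constant).
# `valid` marks raw-valid samples; invalid samples get NA coordinates.
make_trace <- function(x, valid = rep(TRUE, length(x)),
                       rate_hz = 300, second_onset_ms = 1000,
                       target_side = "right", y = 0.5,
                       subject = "t", trial = 1L, condition = "c") {
  n <- length(x)
  xr <- ifelse(valid, x, NA_real_)
  samples <- data.frame(time_us = grid_us(n, rate_hz),
                        x_raw = xr,
                        y_raw = ifelse(valid, rep(y, n), NA_real_),
                        valid_raw = valid)
  gaze_trace(subject, trial, condition, target_side,
             first_onset_us = 0, second_onset_us = second_onset_ms * 1000,
             samples = samples, rate_hz = rate_hz)
}

# A clean 2000-ms trace fixating 0.5 that exits toward `target` such that
# the last in-AOI sample sits at `srt_ms` after the 1000-ms second onset.
make_shift_trace <- function(srt_ms, target_side = "right",
                             rate_hz = 300, n = 601) {
  t_us <- grid_us(n, rate_hz)
  out_x <- if (target_side == "right") 0.9 else 0.1
  x <- ifelse(t_us <= 1000 * 1000 + srt_ms * 1000, 0.5, out_x)
  make_trace(x, rate_hz = rate_hz, target_side = target_side)
}

# Independent naive moving median with end replication (loops, no runmed).
naive_median_filter <- function(z, window) {
  n <- length(z)
  k <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (i - k):(i + k)
    vals <- z[pmin(pmax(idx, 1L), n)]   # replicate first/last value
    out[i] <- median(vals)
  }
  out
}

# Independent per-sample AOI scan for SRT detection (plain loop).
naive_detect <- function(trace, params) {
  s <- trace$samples
  on <- trace$second_onset_us
  thr <- params$edge_threshold
  last_in_us <- NA_real_
  for (i in seq_len(nrow(s))) {
    t <- s$time_us[i]
    x <- s$x[i]
    if (t < on) {
      if (!is.na(x) && x >= thr && x <= 1 - thr) last_in_us <- t
      next
    }
    if (t > on + params$srt_max_ms * 1000) break
    if (is.na(x)) next
    inside <- x >= thr && x <= 1 - thr
    if (inside) { last_in_us <- t; next }
    side <- if (x > 1 - thr) "right" else "left"
    if (side != trace$target_side)
      return(list(status = "rejected_wrong_direction", srt_ms = NA_real_))
    if (is.na(last_in_us))
      return(list(status = "rejected_anticipatory", srt_ms = NA_real_))
    srt <- (last_in_us - on) / 1000
    if (srt < params$srt_min_ms)
      return(list(status = "rejected_anticipatory", srt_ms = NA_real_))
    return(list(status = "valid_shift", srt_ms = srt))
  }
  list(status = "no_shift", srt_ms = params$srt_max_ms)
}

# Quick trial-result rows for aggregate tests.
fake_results <- function(srt_ms, status = rep("valid_shift", length(srt_ms)),
                         subject = "s1", condition = "c1") {
  data.frame(subject_id = subject, trial_number = seq_along(status),
             condition = condition, target_side = "right",
             status = status, srt_ms = srt_ms,
             longest_gap_ms = 0, fixation_prop = 1,
             stringsAsFactors = FALSE)
}
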