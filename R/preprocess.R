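#' Fill missing-data gaps by forward continuation
#'
#' Every invalid sample that has at least one valid predecessor takes the
#' most recent valid coordinates and is flagged `interpolated`; the routine
#' is applied to all periods of missing data regardless of their duration
#' (the post-analysis interpolation cap rejects trials the filling made
#' unreliable). A leading run with no valid predecessor stays missing and
#' produces no record. Valid samples are never altered.
#'
#' Gap duration counts one nominal sample period per missing sample
#' (`(time[end] - time[start]) + 1/rate`), so a 3-sample gap at 300 Hz is
#' 10 ms regardless of timestamp jitter.
#'
#' @param trace A [gaze_trace] whose samples have been eye-combined.
#' @return List with elements `trace` (filled trace) and `records`
#'   (`data.frame` of maximal filled gaps: `start_index`, `end_index`,
#'   `start_time_us`, `end_time_us`, `duration_ms`). A trace with zero valid
#'   samples is returned unchanged with attribute `all_invalid = TRUE` on
#'   the trace, which forces downstream rejection.
#' @export
interpolate_gaps <- function(trace) {
  s <- trace$samples
  n <- nrow(s)
  records <- data.frame(start_index = integer(), end_index = integer(),
                        start_time_us = numeric(), end_time_us = numeric(),
                        duration_ms = numeric())
  if (n == 0) return(list(trace = trace, records = records))
  valid <- s$valid_raw
  if (!any(valid)) {
    attr(trace, "all_invalid") <- TRUE
    return(list(trace = trace, records = records))
  }
  vidx <- which(valid)
  has_pred <- findInterval(seq_len(n), vidx) > 0
  fill <- !valid & has_pred
  src <- vidx[findInterval(which(fill), vidx)]
  s$x <- ifelse(valid, s$x_raw, NA_real_)
  s$y <- ifelse(valid, s$y_raw, NA_real_)
  s$x[fill] <- s$x_raw[src]
  s$y[fill] <- s$y_raw[src]
  s$interpolated <- fill
  trace$samples <- s
  if (any(fill)) {
    r <- rle(fill)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    period_ms <- 1000 / trace$rate_hz
    records <- data.frame(
      start_index = starts[gi],
      end_index = ends[gi],
      start_time_us = s$time_us[starts[gi]],
      end_time_us = s$time_us[ends[gi]],
      duration_ms = (s$time_us[ends[gi]] - s$time_us[starts[gi]]) / 1000 +
        period_ms
    )
  }
  list(trace = trace, records = records)
}

# Exact moving median with end replication: the sequence is virtually
# extended at both ends by repeating its first/last value so the filter
# covers the whole period. runmed on the padded vector yields exact
# windowed medians at every original index.
moving_median <- function(z, window) {
  n <- length(z)
  if (window == 1L || n <= 1L) return(z)
  k <- (window - 1L) %/% 2L
  zp <- c(rep(z[1], k), z, rep(z[n], k))
  stats::runmed(zp, window, endrule = "keep")[(k + 1L):(k + n)]
}

#' Apply a moving median filter to a gaze trace
#'
#' Filters x and y independently with a centered odd-length window; both
#' ends of the analysis period are handled by replicating the first/last
#' available sample so the filter applies over the whole period. Timestamps,
#' validity and interpolation flags are untouched. A leading missing run
#' (no valid predecessor) is left missing and filtering starts at the first
#' available sample.
#'
#' @param trace An interpolated [gaze_trace] (no interior missing values).
#' @param window_samples Odd window length in samples (default from
#'   `params`); the default 37 samples spans 123 ms at 300 Hz.
#' @return The filtered trace.
#' @export
median_filter <- function(trace, window_samples = 37L) {
  window_samples <- as.integer(window_samples)
  if (window_samples < 1L || window_samples %% 2L == 0L)
    stop("median filter window must be an odd integer >= 1", call. = FALSE)
  s <- trace$samples
  n <- nrow(s)
  if (n == 0) return(trace)
  if (window_samples > 2L * n)
    stop("median filter window (", window_samples,
         ") longer than twice the trace (", n, " samples)", call. = FALSE)
  avail <- which(!is.na(s$x))
  if (!length(avail)) return(trace)
  i0 <- avail[1]
  if (anyNA(s$x[i0:n]))
    stop("trace has interior missing values; interpolate before filtering",
         call. = FALSE)
  idx <- i0:n
  s$x[idx] <- moving_median(s$x[idx], window_samples)
  s$y[idx] <- moving_median(s$y[idx], window_samples)
  trace$samples <- s
  trace
}

#' Preprocess a trace: interpolate then median-filter
#'
#' Convenience wrapper running [interpolate_gaps] and [median_filter] with
#' the configured window.
#'
#' @param trace An eye-combined [gaze_trace].
#' @param params An [srt_params] object.
#' @return List with `trace` (preprocessed) and `records` (interpolation
#'   records).
#' @export
preprocess_trace <- function(trace, params = srt_params()) {
  ip <- interpolate_gaps(trace)
  if (isTRUE(attr(ip$trace, "all_invalid")) || nrow(ip$trace$samples) == 0)
    return(ip)
  ip$trace <- median_filter(ip$trace, params$filter_window_samples)
  ip
}
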