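#' Analysis parameters for SRT extraction
#'
#' Bundles every user-defined threshold of the SRT pipeline. Defaults follow
#' the settings established for a typical infant disengagement paradigm
#' sampled at 300 Hz: a 900--1100 ms first-stimulus window, a 37-sample
#' (123 ms) median filter, validity codes 0--1 accepted, a central AOI
#' bounded 30% from each screen edge, a 200 ms cap on interpolated segments,
#' a .70 minimum fixation proportion, and a 150--1000 ms acceptance window
#' for the saccade latency.
#'
#' All user-facing durations are milliseconds; they are converted to the
#' microsecond timebase of the recordings internally.
#'
#' @param valid_codes Integer validity codes accepted as reliable tracking
#'   (tracker convention: 0 best, 4 untracked).
#' @param filter_window_samples Odd length of the moving median filter, in
#'   samples. Ignored when `filter_window_ms` is given.
#' @param filter_window_ms Optional filter length in milliseconds, converted
#'   to the nearest odd sample count at `rate_hz`.
#' @param max_gap_ms Upper limit for any interpolated segment overlapping the
#'   analysis period.
#' @param min_first_ms,max_first_ms Accepted span of recorded data during the
#'   first-stimulus phase.
#' @param min_second_ms Minimum span of recorded data during the
#'   second-stimulus phase.
#' @param min_fixation_prop Minimum proportion of first-phase samples
#'   (interpolated samples included) inside the central AOI.
#' @param srt_min_ms,srt_max_ms Shortest and longest acceptable saccade
#'   latency, relative to second-stimulus onset.
#' @param edge_threshold Fraction of the normalized x extent defining the
#'   central AOI as `[edge_threshold, 1 - edge_threshold]`.
#' @param rate_hz Nominal sampling rate, used for sample-period arithmetic.
#' @param min_scorable_trials Minimum scorable trials per subject-condition
#'   group before a summary is flagged insufficient.
#' @param display_span_deg Horizontal visual angle subtended by the display,
#'   used only for degree conversions in quality reporting.
#' @return An object of class `srt_params` (a validated named list).
#' @examples
#' p <- srt_params()
#' p$filter_window_samples            # 37
#' srt_params(filter_window_ms = 123)$filter_window_samples
#' @export
srt_params <- function(valid_codes = c(0L, 1L),
                       filter_window_samples = 37L,
                       filter_window_ms = NULL,
                       max_gap_ms = 200,
                       min_first_ms = 900,
                       max_first_ms = 1100,
                       min_second_ms = 1000,
                       min_fixation_prop = 0.70,
                       srt_min_ms = 150,
                       srt_max_ms = 1000,
                       edge_threshold = 0.30,
                       rate_hz = 300,
                       min_scorable_trials = 3L,
                       display_span_deg = 46) {
  if (!is.null(filter_window_ms)) {
    w <- round(filter_window_ms * rate_hz / 1000)
    if (w %% 2 == 0) w <- w + 1            # nearest odd, rounding up on ties
    filter_window_samples <- as.integer(max(1L, w))
  }
  filter_window_samples <- as.integer(filter_window_samples)
  if (length(valid_codes) < 1L || !all(valid_codes %in% 0:4))
    stop("valid_codes must be a nonempty subset of 0:4", call. = FALSE)
  if (filter_window_samples < 1L || filter_window_samples %% 2L == 0L)
    stop("filter_window_samples must be an odd integer >= 1", call. = FALSE)
  if (!(srt_min_ms < srt_max_ms))
    stop("srt_min_ms must be smaller than srt_max_ms", call. = FALSE)
  if (!(min_fixation_prop > 0 && min_fixation_prop <= 1))
    stop("min_fixation_prop must lie in (0, 1]", call. = FALSE)
  if (!(min_first_ms <= max_first_ms))
    stop("min_first_ms must not exceed max_first_ms", call. = FALSE)
  if (!(edge_threshold > 0 && edge_threshold < 0.5))
    stop("edge_threshold must lie in (0, 0.5)", call. = FALSE)
  if (max_gap_ms < 0 || min_second_ms < 0 || rate_hz <= 0)
    stop("durations must be nonnegative and rate_hz positive", call. = FALSE)
  structure(list(
    valid_codes = as.integer(valid_codes),
    filter_window_samples = filter_window_samples,
    max_gap_ms = max_gap_ms,
    min_first_ms = min_first_ms,
    max_first_ms = max_first_ms,
    min_second_ms = min_second_ms,
    min_fixation_prop = min_fixation_prop,
    srt_min_ms = srt_min_ms,
    srt_max_ms = srt_max_ms,
    edge_threshold = edge_threshold,
    rate_hz = rate_hz,
    min_scorable_trials = as.integer(min_scorable_trials),
    display_span_deg = display_span_deg
  ), class = "srt_params")
}

#' @export
print.srt_params <- function(x, ...) {
  cat("SRT analysis parameters\n")
  cat(sprintf("  valid codes:        {%s}\n", paste(x$valid_codes, collapse = ",")))
  cat(sprintf("  median filter:      %d samples (%.1f ms at %g Hz)\n",
              x$filter_window_samples, filter_window_ms(x), x$rate_hz))
  cat(sprintf("  first stimulus:     %g-%g ms; second >= %g ms\n",
              x$min_first_ms, x$max_first_ms, x$min_second_ms))
  cat(sprintf("  interpolation cap:  %g ms\n", x$max_gap_ms))
  cat(sprintf("  min fixation:       %.2f\n", x$min_fixation_prop))
  cat(sprintf("  SRT window:         %g-%g ms\n", x$srt_min_ms, x$srt_max_ms))
  cat(sprintf("  central AOI:        x in [%.2f, %.2f]\n",
              x$edge_threshold, 1 - x$edge_threshold))
  invisible(x)
}

#' Median-filter length in milliseconds
#'
#' @param params An `srt_params` object.
#' @return Filter length in ms at the configured sampling rate (a 37-sample
#'   window at 300 Hz spans 123.3 ms).
#' @export
filter_window_ms <- function(params) {
  params$filter_window_samples * 1000 / params$rate_hz
}

#' Convert a normalized x displacement to degrees of visual angle
#'
#' Linear small-angle mapping: degrees = normalized units x display span.
#'
#' @param dx Displacement in normalized screen units (fraction of width).
#' @param display_span_deg Horizontal visual angle of the display (degrees).
#' @return Displacement in degrees.
#' @examples
#' norm_to_degrees(0.5, 46)   # 23
#' @export
norm_to_degrees <- function(dx, display_span_deg = 46) {
  dx * display_span_deg
}

#' Central area-of-interest membership
#'
#' The central AOI is the band `edge_threshold <= x <= 1 - edge_threshold`;
#' boundary samples count as inside. One convention, applied everywhere
#' (detection, border check, fixation check).
#'
#' @param x Normalized x coordinate(s); `NA` yields `NA`.
#' @param edge_threshold Fraction of the x extent cut from each edge.
#' @return Logical vector of membership.
#' @export
in_central_aoi <- function(x, edge_threshold = 0.30) {
  x >= edge_threshold & x <= 1 - edge_threshold
}

# Classify x into the three horizontal regions; NA stays NA.
aoi_region <- function(x, edge_threshold = 0.30) {
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x < edge_threshold] <- "left"
  out[!is.na(x) & x > 1 - edge_threshold] <- "right"
  out[!is.na(x) & x >= edge_threshold & x <= 1 - edge_threshold] <- "central"
  out
}

# Exit side label for a target, given the side string stored on a trace.
stopifnot_side <- function(side) {
  if (!side %in% c("left", "right"))
    stop("target_side must be 'left' or 'right'", call. = FALSE)
  side
}
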