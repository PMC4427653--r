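#' Mean saccadic reaction time over valid shifts
#'
#' Arithmetic mean of `srt_ms` over trials with status `valid_shift` only:
#' trials without gaze shifts and trials rejected by the verification checks
#' are excluded. `NA` when no valid shift exists.
#'
#' @param results Trial-result `data.frame`.
#' @return Mean SRT in ms, or `NA_real_`.
#' @export
mean_srt <- function(results) {
  x <- results$srt_ms[results$status == "valid_shift"]
  if (!length(x)) return(NA_real_)
  mean(x)
}

#' Dwell-time SRT index
#'
#' Combines shift and no-shift trials into the mean proportion of the
#' acceptance window during which gaze dwelt on the first stimulus:
#'
#' \deqn{\mathrm{index} = \frac{1}{n}\sum_{i=1}^{n}
#'   \left(1 - \frac{s_{max} - x_i}{s_{max} - s_{min}}\right)}
#'
#' where \eqn{x_i} is trial *i*'s latency in ms (a no-shift trial
#' contributes \eqn{x_i = s_{max}}), and \eqn{s_{min}}, \eqn{s_{max}} are
#' the shortest and longest acceptable SRTs. With the 150--1000 ms defaults
#' the denominator is 850 ms; all-minimum latencies give 0 and all no-shift
#' trials give 1. Scorable latencies below `srt_min_ms` cannot occur
#' (rejected upstream as anticipatory), so the index never leaves `[0, 1]`;
#' this is asserted, not clamped.
#'
#' @param results Trial-result `data.frame`; only scorable rows
#'   (`valid_shift`, `no_shift`) enter the index.
#' @param params An [srt_params] object supplying the window.
#' @return Index in `[0, 1]`, or `NA_real_` (with a message) when no
#'   scorable trial exists.
#' @examples
#' res <- data.frame(status = c("valid_shift", "no_shift"),
#'                   srt_ms = c(300, 1000))
#' srt_index(res)   # (150/850 + 850/850)/2
#' @export
srt_index <- function(results, params = srt_params()) {
  sc <- results$status %in% c("valid_shift", "no_shift")
  x <- ifelse(results$status[sc] == "no_shift",
              params$srt_max_ms, results$srt_ms[sc])
  if (!length(x)) {
    message("srt_index: no scorable trials")
    return(NA_real_)
  }
  if (any(x < params$srt_min_ms | x > params$srt_max_ms))
    stop("scorable latency outside the acceptance window; ",
         "was detection run with the same parameters?", call. = FALSE)
  span <- params$srt_max_ms - params$srt_min_ms
  sum(1 - (params$srt_max_ms - x) / span) / length(x)
}

#' Summarize trials per subject and condition
#'
#' One row per subject-by-condition group: counts of valid shifts, no-shift
#' trials and rejections (with a per-reason breakdown), the mean SRT over
#' valid shifts, and the SRT index over scorable trials. Groups with fewer
#' than `params$min_scorable_trials` scorable trials are flagged
#' `insufficient` (the convention used when screening participants for
#' longitudinal analyses).
#'
#' @param results Trial-result `data.frame` carrying `subject_id` and
#'   `condition` on every row.
#' @param params An [srt_params] object.
#' @return `data.frame` with one row per non-empty group.
#' @export
summarize_conditions <- function(results, params = srt_params()) {
  if (nrow(results) == 0)
    return(data.frame(subject_id = character(), condition = character(),
                      n_valid_shift = integer(), n_no_shift = integer(),
                      n_rejected = integer(), n_scorable = integer(),
                      mean_srt_ms = numeric(), srt_index = numeric(),
                      insufficient = logical()))
  key <- interaction(results$subject_id, results$condition, drop = TRUE)
  groups <- split(results, key)
  rows <- lapply(groups, function(g) {
    nv <- sum(g$status == "valid_shift")
    nn <- sum(g$status == "no_shift")
    nr <- nrow(g) - nv - nn
    reasons <- table(g$status[!(g$status %in% c("valid_shift", "no_shift"))])
    data.frame(
      subject_id = g$subject_id[1],
      condition = g$condition[1],
      n_valid_shift = nv,
      n_no_shift = nn,
      n_rejected = nr,
      n_scorable = nv + nn,
      mean_srt_ms = mean_srt(g),
      srt_index = suppressMessages(srt_index(g, params)),
      insufficient = (nv + nn) < params$min_scorable_trials,
      rejection_reasons = paste(sprintf("%s:%d", names(reasons), reasons),
                                collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$condition), , drop = FALSE]
}
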