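# A 2000-ms trace (601 samples) covers a 1000-ms first phase and a 1000-ms
# second phase exactly under the span + one-period convention.

test_that("stimulus-duration check brackets both phases", {
  params <- srt_params()
  full <- make_trace(rep(0.5, 601))
  expect_true(check_durations(full, params)$pass)

  # first phase spanning only 850 ms (starts 150 ms late)
  late <- make_trace(rep(0.5, 601))
  late$samples <- late$samples[late$samples$time_us >= 150000, ]
  chk <- check_durations(late, params)
  expect_false(chk$pass)
  expect_lt(chk$first_ms, 900)

  # truncated second phase
  short2 <- make_trace(rep(0.5, 450))   # ends ~497 ms after onset
  expect_false(check_durations(short2, params)$pass)

  empty <- make_trace(numeric(0))
  expect_false(check_durations(empty, params)$pass)
})

test_that("interpolation cap fails only on overlapping long gaps", {
  params <- srt_params()
  tr <- make_trace(rep(0.5, 601))
  rec <- function(duration_ms, start_ms) {
    data.frame(start_index = 1, end_index = 2,
               start_time_us = start_ms * 1000,
               end_time_us = (start_ms + duration_ms) * 1000 - 3333,
               duration_ms = duration_ms)
  }
  expect_true(check_interpolation(rec(190, 500), tr, params)$pass)
  chk <- check_interpolation(rec(230, 500), tr, params)
  expect_false(chk$pass)
  expect_equal(chk$longest_gap_ms, 230)
  # the same 230-ms gap entirely after the analysis window is ignored
  expect_true(check_interpolation(rec(230, 2500), tr, params)$pass)
  expect_equal(check_interpolation(rec(230, 2500), tr, params)$longest_gap_ms, 0)
})

test_that("border violation compares raw flanking samples per gap", {
  params <- srt_params()
  x <- rep(0.5, 601)
  # gap 1 flanked centrally, gap 2 re-appears on the target side
  valid <- rep(TRUE, 601)
  valid[100:120] <- FALSE
  x[99] <- 0.50; x[121] <- 0.52
  valid[400:430] <- FALSE
  x[399] <- 0.50; x[431] <- 0.90
  tr <- make_trace(ifelse(valid, x, NA), valid = valid)
  ip <- interpolate_gaps(tr)
  chk <- check_border_violation(ip$trace, ip$records, params)
  expect_false(chk$pass)
  expect_equal(chk$violating_gap, 2L)

  # same-side flanks pass; a trailing gap with no return cannot violate
  valid2 <- rep(TRUE, 601); valid2[550:601] <- FALSE
  x2 <- rep(0.5, 601)
  tr2 <- make_trace(ifelse(valid2, x2, NA), valid = valid2)
  ip2 <- interpolate_gaps(tr2)
  expect_true(check_border_violation(ip2$trace, ip2$records, params)$pass)
})

test_that("minimum-fixation proportion counts interpolated samples inclusively", {
  params <- srt_params()
  # 300 samples in [0, 1000 ms): place exactly 210 inside the central band
  make_fix_trace <- function(n_inside) {
    x <- c(rep(0.5, n_inside), rep(0.9, 300 - n_inside), rep(0.5, 301))
    make_trace(x)
  }
  at <- check_min_fixation(make_fix_trace(210), params)
  expect_equal(at$fixation_prop, 0.70)
  expect_true(at$pass)                              # inclusive bound
  below <- check_min_fixation(make_fix_trace(207), params)
  expect_equal(below$fixation_prop, 0.69)
  expect_false(below$pass)
  full <- check_min_fixation(make_fix_trace(300), params)
  expect_equal(full$fixation_prop, 1.0)
  expect_false(check_min_fixation(make_trace(numeric(0)), params)$pass)
  # interpolated samples count as available fixation
  valid <- rep(TRUE, 601); valid[50:200] <- FALSE
  tr <- make_trace(ifelse(valid, 0.5, NA), valid = valid)
  ip <- interpolate_gaps(tr)
  expect_equal(check_min_fixation(ip$trace, params)$fixation_prop, 1.0)
})

test_that("verification applies checks in order and reports one reason", {
  params <- srt_params()
  tr <- make_shift_trace(350)
  ip <- interpolate_gaps(tr)
  det <- detect_srt(tr, params)
  clean <- verify_trial(tr, ip$records, det, params)
  expect_equal(clean$status, "valid_shift")
  expect_equal(clean$srt_ms, 350)
  expect_equal(clean$longest_gap_ms, 0)

  # construct a trial failing both duration and fixation: duration wins
  bad <- make_trace(rep(0.9, 601))
  bad$samples <- bad$samples[bad$samples$time_us >= 300000, ]
  res <- verify_trial(bad, interpolate_gaps(bad)$records,
                      detect_srt(bad, params), params)
  expect_equal(res$status, "rejected_duration")
  expect_true(is.na(res$srt_ms))

  # a no_shift passing everything keeps its sentinel
  ns <- make_trace(rep(0.5, 601))
  res2 <- verify_trial(ns, interpolate_gaps(ns)$records,
                       detect_srt(ns, params), params)
  expect_equal(res2$status, "no_shift")
  expect_equal(res2$srt_ms, 1000)
})

test_that("verification is idempotent", {
  params <- srt_params()
  set.seed(31)
  for (rep in 1:20) {
    valid <- runif(601) > 0.1
    x <- 0.5 + cumsum(rnorm(601, 0, 0.01))
    tr <- make_trace(ifelse(valid, x, NA), valid = valid)
    ip <- interpolate_gaps(tr)
    once <- verify_trial(ip$trace, ip$records,
                         detect_srt(ip$trace, params), params)
    twice <- verify_trial(ip$trace, ip$records, once, params)
    expect_equal(once, twice)
  }
})

test_that("tightening thresholds never converts rejection into acceptance", {
  set.seed(37)
  scorable <- function(res) res$status %in% c("valid_shift", "no_shift")
  for (rep in 1:40) {
    valid <- runif(601) > runif(1, 0.05, 0.4)
    x <- 0.5 + cumsum(rnorm(601, 0, runif(1, 0.002, 0.03)))
    tr <- make_trace(ifelse(valid, x, NA), valid = valid)
    ip <- interpolate_gaps(tr)
    loose <- srt_params(max_gap_ms = runif(1, 150, 400),
                        min_fixation_prop = runif(1, 0.4, 0.7),
                        min_first_ms = runif(1, 700, 900),
                        min_second_ms = runif(1, 800, 1000))
    tight <- loose
    tight$max_gap_ms <- loose$max_gap_ms * runif(1, 0.4, 1)
    tight$min_fixation_prop <- min(1, loose$min_fixation_prop + runif(1, 0, 0.3))
    tight$min_first_ms <- loose$min_first_ms + runif(1, 0, 100)
    tight$min_second_ms <- loose$min_second_ms + runif(1, 0, 100)
    det <- detect_srt(ip$trace, loose)
    res_loose <- verify_trial(ip$trace, ip$records, det, loose)
    res_tight <- verify_trial(ip$trace, ip$records, det, tight)
    if (!scorable(res_loose)) expect_false(scorable(res_tight))
  }
})
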