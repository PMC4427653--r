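test_that("quality segments end at the saccade or at 2000 ms", {
  tr <- make_shift_trace(350)
  res <- detect_srt(tr, srt_params())
  seg <- excerpt_quality_segment(tr, res)
  expect_equal(max(seg$time_us), 1000000 + 350000)
  expect_equal(min(seg$time_us), 0)

  ns <- make_trace(rep(0.5, 601))                  # 2000-ms trace
  seg2 <- excerpt_quality_segment(ns, detect_srt(ns, srt_params()))
  expect_equal(nrow(seg2), 601)                    # clipped to the trial
  long <- make_trace(rep(0.5, 901))                # 3000-ms trace, no shift
  seg3 <- excerpt_quality_segment(long, detect_srt(long, srt_params()))
  expect_lte(max(seg3$time_us), 2000 * 1000)
})

test_that("precision RMS matches hand values and scales with jitter", {
  const <- make_trace(rep(0.5, 100))$samples
  expect_equal(precision_rms(const), 0)
  alt <- make_trace(rep(c(0.50, 0.51), 50))$samples
  expect_equal(precision_rms(alt), 0.01, tolerance = 1e-12)
  # white jitter of sd sigma per axis has large-sample RMS 2*sigma
  set.seed(47)
  sigma <- 0.013
  jit <- make_trace(0.5 + rnorm(10000, 0, sigma),
                    y = 0.5)$samples
  jit$y_raw <- 0.5 + rnorm(10000, 0, sigma)
  expect_equal(precision_rms(jit), 2 * sigma, tolerance = 0.05 * 2 * sigma)
  # translation invariance and linear scaling
  shifted <- jit; shifted$x_raw <- shifted$x_raw + 0.2
  expect_equal(precision_rms(shifted), precision_rms(jit))
  scaled <- jit
  scaled$x_raw <- 0.5 + 3 * (scaled$x_raw - 0.5)
  scaled$y_raw <- 0.5 + 3 * (scaled$y_raw - 0.5)
  expect_equal(precision_rms(scaled), 3 * precision_rms(jit), tolerance = 1e-12)
  # gaps break pairs; too few pairs -> NA
  one <- make_trace(c(0.5, NA, 0.6), valid = c(TRUE, FALSE, TRUE))$samples
  expect_true(is.na(precision_rms(one)))
  expect_equal(attr(precision_rms(alt, display_span_deg = 46), "degrees"),
               0.46, tolerance = 1e-9)
})

test_that("robustness is the missing proportion, blind to coordinates", {
  v <- c(rep(TRUE, 270), rep(FALSE, 30))
  seg <- make_trace(ifelse(v, 0.5, NA), valid = v)$samples
  expect_equal(robustness(seg), 0.10)
  expect_equal(robustness(make_trace(rep(0.1, 5))$samples), 0)
  allbad <- make_trace(rep(NA_real_, 5), valid = rep(FALSE, 5))$samples
  expect_equal(robustness(allbad), 1)
  seg2 <- seg; seg2$x_raw <- seg2$x_raw * 10
  expect_equal(robustness(seg2), robustness(seg))
})

test_that("segment durations are run lengths at the nominal rate", {
  tr <- make_trace(rep(0.5, 300))
  expect_equal(segment_durations(tr), 1000)
  v <- rep(c(TRUE, FALSE, TRUE), c(30, 10, 60))
  tr2 <- make_trace(ifelse(v, 0.5, NA), valid = v)
  expect_equal(segment_durations(tr2), c(100, 200))
  none <- make_trace(rep(NA_real_, 5), valid = rep(FALSE, 5))
  expect_length(segment_durations(none), 0)
})

test_that("the Pearson chi-square matches the hand formula and degenerates", {
  even <- matrix(c(50, 50, 450, 450), 2,
                 dimnames = list(c("high", "low"), c("large", "small")))
  cs <- gazesrt:::pearson_chisq(even)
  expect_equal(cs$statistic, 0)
  # sum((O-E)^2/E) with margins 100/100 x 50/150: E = [[25,75],[25,75]]
  skew <- matrix(c(10, 40, 90, 60), 2,
                 dimnames = list(c("high", "low"), c("large", "small")))
  expect_equal(gazesrt:::pearson_chisq(skew)$statistic, 24.0)
  degen <- matrix(c(0, 0, 100, 100), 2)
  bad <- gazesrt:::pearson_chisq(degen)
  expect_true(is.na(bad$statistic))
  expect_match(bad$reason, "degenerate")
})

test_that("gap-straddling saccades always trip the border check", {
  params <- srt_params()
  set.seed(53)
  hits <- 0; n_cases <- 60
  for (rep in 1:n_cases) {
    srt <- runif(1, 200, 800)
    tr <- make_shift_trace(srt)
    # carve a gap over the crossing so raw flanks straddle the boundary
    cross_idx <- which(tr$samples$x_raw > 0.7)[1]
    lo <- max(2, cross_idx - sample(3:20, 1))
    hi <- min(nrow(tr$samples) - 1, cross_idx + sample(3:20, 1))
    tr$samples$valid_raw[lo:hi] <- FALSE
    tr$samples$x_raw[lo:hi] <- NA
    tr$samples$y_raw[lo:hi] <- NA
    tr$samples$x <- ifelse(tr$samples$valid_raw, tr$samples$x_raw, NA)
    tr$samples$y <- ifelse(tr$samples$valid_raw, tr$samples$y_raw, NA)
    ip <- interpolate_gaps(tr)
    if (!check_border_violation(ip$trace, ip$records, params)$pass)
      hits <- hits + 1
  }
  expect_equal(hits, n_cases)
})

test_that("full and typical modes differ as designed on a small benchmark", {
  ex <- run_quality_experiment(n_trials = 150, seed = 61)
  full <- ex$full$per_trial
  typical <- ex$typical$per_trial
  expect_true(mean(full$large_error[!is.na(full$error_ms)]) <
                mean(typical$large_error[!is.na(typical$error_ms)]))
  expect_equal(nrow(ex$full$stats), 2)
  expect_true(all(c("precision", "robustness") %in% names(ex$full$tables)))
  f <- tempfile(fileext = ".csv")
  write_quality_experiment(ex, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 4)                  # 2 metrics x 2 modes
})
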