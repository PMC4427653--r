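write_log <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

log_header <- "time_us,x_left,y_left,x_right,y_right,validity_left,validity_right,marker"

test_that("a well-formed log parses in order with missing cells as NA", {
  f <- write_log(c(log_header,
                   "0,0.5,0.5,0.52,0.5,0,0,s1",
                   "3333,,0.5,0.52,0.5,0,0,s1",
                   "6667,0.5,0.5,0.52,0.5,1,4,s1",
                   "10000,0.5,0.5,0.52,0.5,0,0,s2"))
  d <- read_gaze_log(f)
  expect_equal(nrow(d), 4)
  expect_equal(d$time_us, c(0, 3333, 6667, 10000))
  expect_true(is.na(d$x_left[2]))
  expect_equal(d$validity_left[2], 0L)      # validity retained alongside gap
  expect_equal(d$marker, c("s1", "s1", "s1", "s2"))
})

test_that("time units convert to microseconds and delimiters auto-detect", {
  f <- write_log(c(gsub("time_us", "t_ms", gsub(",", ";", log_header)),
                   "10;0.5;0.5;0.5;0.5;0;0;m"))
  d <- read_gaze_log(f, column_map = list(time = "t_ms"), time_unit = "ms")
  expect_equal(d$time_us, 10000)
})

test_that("structural problems are reported", {
  f <- write_log(c(log_header, "0,0.5,0.5,0.5,0.5,0,0,m"))
  expect_error(read_gaze_log(f, column_map = list(time = "nope")),
               "lacks mapped column")
  f2 <- write_log(c(log_header,
                    "0,0.5,0.5,0.5,0.5,0,0,m",
                    "5000,0.5,0.5,0.5,0.5,0,0,m",
                    "4000,0.5,0.5,0.5,0.5,0,0,m"))
  expect_error(read_gaze_log(f2), "row 3")
  expect_error(read_gaze_log(tempfile()), "not found")
})

test_that("rows with unparseable timestamps are dropped with a count", {
  f <- write_log(c(log_header,
                   "0,0.5,0.5,0.5,0.5,0,0,m",
                   "bogus,0.5,0.5,0.5,0.5,0,0,m",
                   "9000,0.5,0.5,0.5,0.5,0,0,m"))
  expect_message(d <- read_gaze_log(f), "1 row")
  expect_equal(nrow(d), 2)
})

test_that("segmentation partitions samples into analysis windows", {
  params <- srt_params()
  ds <- generate_gaze_dataset(synth_config(noise_sd = 0, gap_rate = 0,
                                           spike_rate = 0),
                              n_subjects = 1, n_trials = 3, seed = 5)
  p <- write_gaze_dataset(ds, file.path(tempdir(), "segtest"))
  samples <- read_gaze_log(p["gaze"])
  tt <- read.csv(p["trials"])
  traces <- segment_trials(samples, tt, params)
  expect_length(traces, 3)
  # window [first_onset, second_onset + srt_max]: 601 grid samples at 300 Hz
  expect_equal(vapply(traces, function(tr) nrow(tr$samples), integer(1)),
               rep(601L, 3))
  # partition: no sample in two traces, every in-window sample assigned
  all_times <- unlist(lapply(traces, function(tr) tr$samples$time_us))
  expect_equal(anyDuplicated(all_times), 0)
  for (i in 1:3) {
    in_win <- samples$time_us >= tt$first_onset_us[i] &
      samples$time_us <= tt$second_onset_us[i] + params$srt_max_ms * 1000
    expect_equal(sum(in_win), nrow(traces[[i]]$samples))
  }
})

test_that("marker-based onsets resolve and absent markers skip the trial", {
  f <- write_log(c(log_header,
                   paste0(grid_us(900), ",0.5,0.5,0.5,0.5,0,0,",
                          rep(c("p1", "p2"), c(300, 600)))))
  samples <- read_gaze_log(f)
  tt <- data.frame(subject_id = "s1", trial_number = 1:2,
                   condition = "c", target_side = "right",
                   first_marker = c("p1", "p1"),
                   second_marker = c("p2", "never"),
                   stringsAsFactors = FALSE)
  expect_warning(traces <- segment_trials(samples, tt, srt_params()),
                 "unsegmentable")
  expect_length(traces, 1)
  expect_equal(traces[[1]]$second_onset_us, samples$time_us[301])
})

test_that("trial results serialize with empty cells for rejected SRTs", {
  res <- fake_results(c(350, NA, 1000),
                      status = c("valid_shift", "rejected_border", "no_shift"))
  f <- tempfile(fileext = ".csv")
  write_trial_results(res, f)
  lines <- readLines(f)
  expect_length(lines, 4)                     # header + 3 rows
  back <- read.csv(f)
  expect_true(is.na(back$srt_ms[2]))
  expect_equal(back$status[2], "rejected_border")
  # empty result list -> header only
  f2 <- tempfile(fileext = ".csv")
  write_trial_results(res[0, ], f2)
  expect_length(readLines(f2), 1)
})

test_that("summary writes one row per participant with condition column groups", {
  res <- rbind(fake_results(c(300, 500), subject = "s1", condition = "a"),
               fake_results(rep(NA, 2), status = rep("rejected_border", 2),
                            subject = "s1", condition = "b"),
               fake_results(c(400, 1000), status = c("valid_shift", "no_shift"),
                            subject = "s2", condition = "a"),
               fake_results(350, subject = "s2", condition = "b"))
  summ <- summarize_conditions(res)
  f <- tempfile(fileext = ".csv")
  write_summary(summ, f)
  wide <- read.csv(f)
  expect_equal(nrow(wide), 2)
  expect_true(all(c("a_mean_srt_ms", "b_mean_srt_ms", "a_srt_index") %in%
                    names(wide)))
  # zero valid shifts -> count 0, empty mean cell
  expect_equal(wide$b_n_valid_shift[wide$subject_id == "s1"], 0)
  expect_true(is.na(wide$b_mean_srt_ms[wide$subject_id == "s1"]))
  # round-trip reproduces numeric fields to 3 decimals
  expect_equal(wide$a_mean_srt_ms[wide$subject_id == "s1"],
               round(mean(c(300, 500)), 3))
  expect_equal(wide$a_srt_index[wide$subject_id == "s2"],
               round(srt_index(res[res$subject_id == "s2" &
                                     res$condition == "a", ]), 3))
  # duplicate subject x condition is a validation error
  expect_error(write_summary(rbind(summ, summ[1, ]), tempfile()), "duplicate")
})

test_that("parse and re-serialize preserves counts and non-missing values", {
  ds <- generate_gaze_dataset(synth_config(), 1, 2, seed = 9)
  dir <- file.path(tempdir(), "rt")
  p <- write_gaze_dataset(ds, dir)
  d <- read_gaze_log(p["gaze"])
  expect_equal(nrow(d), nrow(ds$samples))
  expect_equal(d$x_left, ds$samples$x_left, tolerance = 1e-12)
  expect_equal(d$validity_right, ds$samples$validity_right)
})
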