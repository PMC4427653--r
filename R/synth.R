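#' Configuration of the synthetic gaze-trace generator
#'
#' The generator emulates the raw-data pathology of infant corneal-reflection
#' recordings in a two-stimulus disengagement trial: fixational coordinate
#' jitter, missing-data gaps, brief large-amplitude spike artifacts, and an
#' abrupt x step at the saccade. Defaults mirror the paradigm the analysis
#' defaults were set for: 300 Hz sampling, a central stimulus shown alone
#' for 1000 ms, a lateral stimulus appearing at 1000 ms and staying for
#' 3000 ms, fixation at screen center, lateral targets at x = 0.9 / 0.1.
#'
#' Missing-data gaps arrive as a Poisson process with log-normal durations;
#' the default rate (2.2/s with mean gap 90 ms) makes the expected missing
#' proportion about 0.18, matching the typical share of missing samples in
#' infant recordings. Spikes jump the reported x to `spike_x` for a few
#' samples while validity stays 0, emulating the transient tracker artifact
#' that a median filter must remove. True latencies are truncated-normal
#' (mean 400 ms, sd 150 ms on [150, 1000]), populating the full acceptance
#' window. Saccades are linear ramps over `saccade_duration_ms` — a stated
#' simplification sufficient for AOI-crossing detection, not a
#' main-sequence velocity profile.
#'
#' @param rate_hz Sampling rate.
#' @param first_ms Duration of the first stimulus shown alone (= second
#'   stimulus onset).
#' @param post_ms Duration of the second stimulus on screen.
#' @param fixation_x,fixation_y Fixation center, normalized units.
#' @param target_x_right,target_x_left Lateral target positions.
#' @param noise_sd Fixational jitter sd per axis, normalized units.
#' @param eye_jitter_sd Additional independent per-eye jitter sd.
#' @param gap_rate Missing-data gap starts per second.
#' @param gap_meanlog,gap_sdlog Log-normal parameters of gap length in ms.
#' @param spike_rate Spike artifacts per second.
#' @param spike_duration_samples Spike length in samples.
#' @param spike_x Coordinate the spike jumps to.
#' @param latency_mean,latency_sd,latency_min,latency_max Truncated-normal
#'   true-latency distribution in ms.
#' @param p_no_shift Probability a trial has no gaze shift.
#' @param p_wrong_direction Probability the saccade goes to the non-target
#'   side.
#' @param saccade_duration_ms Duration of the linear position ramp.
#' @param aoi_threshold Edge threshold defining ground-truth AOI crossing.
#' @param noise_sd_range,gap_rate_range Optional `c(min, max)` ranges; when
#'   set, [generate_gaze_dataset] draws a per-subject value uniformly from
#'   them to create a between-recording quality spread.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(rate_hz = 300,
                         first_ms = 1000,
                         post_ms = 3000,
                         fixation_x = 0.5,
                         fixation_y = 0.5,
                         target_x_right = 0.9,
                         target_x_left = 0.1,
                         noise_sd = 0.01,
                         eye_jitter_sd = 0.002,
                         gap_rate = 2.2,
                         gap_meanlog = log(90) - 0.125,
                         gap_sdlog = 0.5,
                         spike_rate = 0.5,
                         spike_duration_samples = 3L,
                         spike_x = 0,
                         latency_mean = 400,
                         latency_sd = 150,
                         latency_min = 150,
                         latency_max = 1000,
                         p_no_shift = 0.1,
                         p_wrong_direction = 0.05,
                         saccade_duration_ms = 30,
                         aoi_threshold = 0.30,
                         noise_sd_range = NULL,
                         gap_rate_range = NULL) {
  cfg <- as.list(environment())
  stopifnot(rate_hz > 0, first_ms > 0, post_ms > 0,
            gap_rate >= 0, spike_rate >= 0,
            p_no_shift >= 0, p_no_shift <= 1,
            p_wrong_direction >= 0, p_wrong_direction <= 1,
            p_no_shift + p_wrong_direction <= 1,
            latency_min < latency_max)
  structure(cfg, class = "synth_config")
}

# Truncated-normal draw by bounded rejection sampling.
draw_latency <- function(cfg) {
  for (i in 1:100) {
    x <- stats::rnorm(1, cfg$latency_mean, cfg$latency_sd)
    if (x >= cfg$latency_min && x <= cfg$latency_max) return(x)
  }
  stop("latency rejection sampling exhausted (100 draws); ",
       "check latency_mean/sd against the window", call. = FALSE)
}

# Merge integer index intervals (sorted by start) into maximal disjoint runs.
merge_intervals <- function(starts, ends) {
  if (!length(starts)) return(data.frame(start = integer(), end = integer()))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) me <- max(me, ends[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- starts[i]; me <- ends[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Generate one synthetic trial
#'
#' Emits a two-eye raw sample table plus the trial's ground truth. The
#' noiseless x trajectory holds `fixation_x` until the saccade, then ramps
#' linearly to the target over `saccade_duration_ms`. The stored
#' `true_srt_ms` is the analytic AOI-exit latency snapped to the sample
#' grid: the time of the last sample at or before the instant the clean
#' trajectory crosses the AOI boundary, minus second-stimulus onset. A
#' crossing whose first outside sample falls beyond the analysis window is
#' recorded as no-shift ground truth (that is what the windowed method
#' defines), with the programmed latency kept in `latency_ms`.
#'
#' Gaps overwrite both eyes' validity to 4 with missing coordinates; spikes
#' overwrite x with `spike_x` while validity stays 0. Both eyes are the
#' common signal plus small independent jitter.
#'
#' @param config A [synth_config].
#' @param subject_id,trial_number,condition,target_side Trial identity.
#' @param srt_max_ms Analysis-window maximum used for the ground-truth
#'   windowing (default 1000).
#' @param seed Optional integer; when given, seeds the RNG for this trial.
#' @return List with `raw` (two-eye sample `data.frame` incl. `marker`),
#'   `trial` (one trial-table row), `truth` (one ground-truth row), and
#'   `gap_intervals` / `spike_intervals` (sample-index `data.frame`s).
#' @export
generate_trial <- function(config, subject_id = "s01", trial_number = 1L,
                           condition = "overlap", target_side = "right",
                           srt_max_ms = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  period_us <- 1e6 / cfg$rate_hz
  n <- floor((cfg$first_ms + cfg$post_ms) / 1000 * cfg$rate_hz)
  t_us <- round((seq_len(n) - 1) * period_us)
  on2 <- cfg$first_ms * 1000

  u <- stats::runif(1)
  kind <- if (u < cfg$p_no_shift) "no_shift"
    else if (u < cfg$p_no_shift + cfg$p_wrong_direction) "wrong_direction"
    else "shift"
  latency <- if (kind == "no_shift") NA_real_ else draw_latency(cfg)
  move_side <- switch(kind,
                      shift = target_side,
                      wrong_direction = setdiff(c("left", "right"), target_side),
                      no_shift = NA_character_)
  target_x <- if (identical(move_side, "right")) cfg$target_x_right
              else if (identical(move_side, "left")) cfg$target_x_left
              else NA_real_

  x_clean <- rep(cfg$fixation_x, n)
  t_cross_us <- NA_real_
  if (kind != "no_shift") {
    t_sac_us <- on2 + latency * 1000
    ramp_us <- cfg$saccade_duration_ms * 1000
    frac <- pmin(pmax((t_us - t_sac_us) / ramp_us, 0), 1)
    x_clean <- cfg$fixation_x + frac * (target_x - cfg$fixation_x)
    boundary <- if (identical(move_side, "right")) 1 - cfg$aoi_threshold
                else cfg$aoi_threshold
    t_cross_us <- t_sac_us +
      ramp_us * (boundary - cfg$fixation_x) / (target_x - cfg$fixation_x)
  }

  # Ground truth on the sample grid, windowed as the method defines it.
  win_end_us <- on2 + srt_max_ms * 1000
  if (kind == "shift") {
    t_out_us <- t_us[t_us > t_cross_us][1]        # first strictly-outside sample
    if (is.na(t_out_us) || t_out_us > win_end_us) {
      truth_kind <- "no_shift"; true_srt <- NA_real_
    } else {
      truth_kind <- "shift"
      true_srt <- (max(t_us[t_us <= t_cross_us]) - on2) / 1000
    }
  } else {
    truth_kind <- kind
    true_srt <- NA_real_
  }

  common_x <- x_clean + stats::rnorm(n, 0, cfg$noise_sd)
  common_y <- cfg$fixation_y + stats::rnorm(n, 0, cfg$noise_sd)
  x_l <- common_x + stats::rnorm(n, 0, cfg$eye_jitter_sd)
  x_r <- common_x + stats::rnorm(n, 0, cfg$eye_jitter_sd)
  y_l <- common_y + stats::rnorm(n, 0, cfg$eye_jitter_sd)
  y_r <- common_y + stats::rnorm(n, 0, cfg$eye_jitter_sd)
  val_l <- val_r <- rep(0L, n)

  dur_s <- (cfg$first_ms + cfg$post_ms) / 1000
  # spike artifacts: abrupt x excursions, validity unaffected
  n_sp <- stats::rpois(1, cfg$spike_rate * dur_s)
  sp_start <- sp_end <- integer()
  if (n_sp > 0) {
    st <- sort(sample.int(n, n_sp))
    en <- pmin(st + cfg$spike_duration_samples - 1L, n)
    for (k in seq_len(n_sp)) {
      x_l[st[k]:en[k]] <- cfg$spike_x
      x_r[st[k]:en[k]] <- cfg$spike_x
    }
    sp <- merge_intervals(st, en)
    sp_start <- sp$start; sp_end <- sp$end
  }
  # missing-data gaps: validity 4, coordinates absent
  n_g <- stats::rpois(1, cfg$gap_rate * dur_s)
  gp_start <- gp_end <- integer()
  if (n_g > 0) {
    st <- sample.int(n, n_g)
    len_ms <- stats::rlnorm(n_g, cfg$gap_meanlog, cfg$gap_sdlog)
    len <- pmax(1L, as.integer(round(len_ms * cfg$rate_hz / 1000)))
    en <- pmin(st + len - 1L, n)
    gp <- merge_intervals(st, en)
    for (k in seq_len(nrow(gp))) {
      i <- gp$start[k]:gp$end[k]
      val_l[i] <- val_r[i] <- 4L
      x_l[i] <- x_r[i] <- y_l[i] <- y_r[i] <- NA_real_
    }
    gp_start <- gp$start; gp_end <- gp$end
  }

  marker <- ifelse(t_us < on2,
                   sprintf("%s_t%03d_s1", subject_id, trial_number),
                   sprintf("%s_t%03d_s2", subject_id, trial_number))
  raw <- data.frame(time_us = t_us, x_left = x_l, y_left = y_l,
                    x_right = x_r, y_right = y_r,
                    validity_left = val_l, validity_right = val_r,
                    marker = marker, stringsAsFactors = FALSE)
  trial <- data.frame(subject_id = subject_id, trial_number = trial_number,
                      condition = condition, target_side = target_side,
                      first_onset_us = 0, second_onset_us = on2,
                      stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = subject_id, trial_number = trial_number,
                      kind = truth_kind,
                      latency_ms = latency,
                      true_srt_ms = true_srt,
                      no_shift = truth_kind == "no_shift",
                      wrong_direction = truth_kind == "wrong_direction",
                      n_gaps = length(gp_start),
                      n_spikes = length(sp_start),
                      stringsAsFactors = FALSE)
  list(raw = raw, trial = trial, truth = truth,
       gap_intervals = data.frame(start = gp_start, end = gp_end),
       spike_intervals = data.frame(start = sp_start, end = sp_end))
}

#' Turn one generated trial into an eye-combined gaze trace
#'
#' @param gen Output of [generate_trial].
#' @param params An [srt_params] (valid codes, rate).
#' @return A [gaze_trace] spanning the analysis period.
#' @export
as_gaze_trace <- function(gen, params = srt_params()) {
  win_end <- gen$trial$second_onset_us +
    max(params$srt_max_ms, params$min_second_ms) * 1000
  raw <- gen$raw[gen$raw$time_us <= win_end, , drop = FALSE]
  combined <- combine_eyes(raw, params$valid_codes)
  gaze_trace(gen$trial$subject_id, gen$trial$trial_number,
             gen$trial$condition, gen$trial$target_side,
             gen$trial$first_onset_us, gen$trial$second_onset_us,
             combined, rate_hz = params$rate_hz)
}

#' Generate a multi-subject synthetic dataset
#'
#' Produces a continuous gaze log (trials concatenated on a strictly
#' increasing clock with 100 ms between trials), a trial table, and a
#' ground-truth table — in exactly the dialects [read_gaze_log] and
#' [segment_trials] consume. When `noise_sd_range` / `gap_rate_range` are
#' set on the config, each subject draws its own jitter sd and gap rate
#' uniformly from the range, creating the between-recording quality spread
#' the sensitivity experiment needs. Fully deterministic under a fixed
#' seed.
#'
#' @param config A [synth_config].
#' @param n_subjects,n_trials Numbers of subjects and trials per subject.
#' @param seed Integer seed fixing the whole dataset.
#' @param conditions Condition labels cycled across trials.
#' @return List with `samples`, `trial_table`, `truth` (`data.frame`s) and
#'   `config`.
#' @export
generate_gaze_dataset <- function(config = synth_config(), n_subjects = 1,
                                  n_trials = 10, seed = 1,
                                  conditions = "overlap") {
  set.seed(seed)
  all_raw <- vector("list", n_subjects * n_trials)
  all_trial <- vector("list", n_subjects * n_trials)
  all_truth <- vector("list", n_subjects * n_trials)
  offset <- 0
  k <- 0L
  gap_between_us <- 100 * 1000
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    cfg <- config
    if (!is.null(config$noise_sd_range))
      cfg$noise_sd <- stats::runif(1, config$noise_sd_range[1],
                                   config$noise_sd_range[2])
    if (!is.null(config$gap_rate_range))
      cfg$gap_rate <- stats::runif(1, config$gap_rate_range[1],
                                   config$gap_rate_range[2])
    for (tr in seq_len(n_trials)) {
      k <- k + 1L
      side <- if (stats::runif(1) < 0.5) "left" else "right"
      cond <- conditions[(tr - 1L) %% length(conditions) + 1L]
      g <- generate_trial(cfg, sid, tr, cond, side)
      g$raw$time_us <- g$raw$time_us + offset
      g$trial$first_onset_us <- g$trial$first_onset_us + offset
      g$trial$second_onset_us <- g$trial$second_onset_us + offset
      offset <- max(g$raw$time_us) + gap_between_us
      all_raw[[k]] <- g$raw
      all_trial[[k]] <- g$trial
      all_truth[[k]] <- g$truth
    }
  }
  list(samples = do.call(rbind, all_raw),
       trial_table = do.call(rbind, all_trial),
       truth = do.call(rbind, all_truth),
       config = config)
}

#' Write a generated dataset to disk
#'
#' Writes `gaze.csv` (raw log), `trials.csv` (trial table) and `truth.csv`
#' (ground truth) into `dir`, byte-deterministically for a fixed dataset.
#'
#' @param dataset Output of [generate_gaze_dataset].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_gaze_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gaze = file.path(dir, "gaze.csv"),
             trials = file.path(dir, "trials.csv"),
             truth = file.path(dir, "truth.csv"))
  data.table::fwrite(dataset$samples, paths["gaze"], na = "")
  data.table::fwrite(dataset$trial_table, paths["trials"], na = "")
  data.table::fwrite(dataset$truth, paths["truth"], na = "")
  invisible(paths)
}
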