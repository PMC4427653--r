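#' Run the full SRT analysis pipeline
#'
#' One call from raw files to the two result CSVs plus a quality report:
#' read the gaze log, segment trials, combine eyes, interpolate, median
#' filter, detect SRTs, apply the verification checks, aggregate per
#' subject and condition, and compute per-trial quality metrics. Per-check
#' rejection counts are reported via `message()`.
#'
#' @param config Either a path to a YAML file or a named list with elements
#'   `gaze_log`, `trial_table`, `out_dir`, and optionally `params` (named
#'   overrides passed to [srt_params]), `column_map` and `time_unit` for
#'   [read_gaze_log].
#' @return Invisibly, a list with `trials`, `summary`, `quality`
#'   (`data.frame`s) and the output paths. Errors (non-zero exit through
#'   the CLI) on malformed config, missing inputs, or zero scorable trials
#'   overall.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("gaze_log", "trial_table", "out_dir"))
    if (is.null(config[[key]]))
      stop("config is missing required key '", key, "'", call. = FALSE)
  params <- do.call(srt_params, as.list(config$params %||% list()))
  for (p in c(config$gaze_log, config$trial_table))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)

  samples <- read_gaze_log(config$gaze_log,
                           column_map = config$column_map,
                           time_unit = config$time_unit %||% "us")
  trial_table <- data.table::fread(config$trial_table, data.table = FALSE,
                                   na.strings = c("", "NA"))
  traces <- segment_trials(samples, trial_table, params)
  if (!length(traces)) stop("no trials could be segmented", call. = FALSE)

  results <- vector("list", length(traces))
  quality <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    pp <- preprocess_trace(traces[[i]], params)
    det <- detect_srt(pp$trace, params)
    results[[i]] <- verify_trial(pp$trace, pp$records, det, params)
    quality[[i]] <- quality_report(pp$trace, results[[i]], params)
  }
  trials <- do.call(rbind, results)
  quality <- do.call(rbind, quality)

  counts <- table(factor(trials$status, levels = SRT_STATUSES))
  message("trial outcomes: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  if (sum(counts[c("valid_shift", "no_shift")]) == 0)
    stop("zero scorable trials; rejections: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)

  summary <- summarize_conditions(trials, params)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  paths <- c(trials = file.path(config$out_dir, "trials.csv"),
             summary = file.path(config$out_dir, "summary.csv"),
             quality = file.path(config$out_dir, "quality.csv"))
  write_trial_results(trials, paths["trials"])
  write_summary(summary, paths["summary"])
  qout <- quality
  qout[vapply(qout, is.numeric, logical(1))] <-
    lapply(qout[vapply(qout, is.numeric, logical(1))], round, digits = 4)
  utils::write.csv(qout, paths["quality"], row.names = FALSE, na = "")
  invisible(list(trials = trials, summary = summary, quality = quality,
                 paths = paths, params = params))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the data-quality sensitivity experiment on synthetic trials
#'
#' Generates `n_trials` single-trial recordings with a per-trial quality
#' spread and runs [quality_split_experiment] in the requested modes on the
#' identical traces. Each trial draws one latent recording-quality factor
#' `q` uniform on `[0, 1]` that scales all three tracking pathologies
#' jointly — fixational jitter sd, missing-data gap rate, and spike-artifact
#' rate interpolate linearly across their ranges as `q` grows. Tracking
#' pathologies co-occur within a recording (a poorly tracked eye yields
#' jittery coordinates, dropouts, and transient artifacts together), and
#' this coupling is what gives the median splits on the measured quality
#' metrics their contrast between good and poor trials.
#'
#' The default spread (jitter sd 0.005--0.05 normalized units, roughly
#' 0.2--2.3 degrees on a 46-degree display; 0.2--4 gaps per second; 0--2
#' spikes per second) spans good to poor infant recording quality.
#'
#' @param n_trials Number of trials.
#' @param seed RNG seed fixing generation.
#' @param params An [srt_params] object.
#' @param config Base [synth_config]; its `noise_sd`, `gap_rate` and
#'   `spike_rate` are overridden per trial by the quality draw.
#' @param noise_sd_range,gap_rate_range,spike_rate_range Endpoints (best to
#'   worst quality) of the per-trial pathology ranges.
#' @param modes Modes to run (`"full"`, `"typical"`).
#' @return Named list of `quality_split` objects, one per mode, plus
#'   attribute `truth`.
#' @export
run_quality_experiment <- function(n_trials = 2000, seed = 1,
                                   params = srt_params(),
                                   config = synth_config(),
                                   noise_sd_range = c(0.005, 0.05),
                                   gap_rate_range = c(0.2, 4),
                                   spike_rate_range = c(0, 2),
                                   modes = c("full", "typical")) {
  set.seed(seed)
  lerp <- function(r, q) r[1] + q * (r[2] - r[1])
  traces <- vector("list", n_trials)
  truth <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- config
    q <- stats::runif(1)
    cfg$noise_sd <- lerp(noise_sd_range, q)
    cfg$gap_rate <- lerp(gap_rate_range, q)
    cfg$spike_rate <- lerp(spike_rate_range, q)
    side <- if (stats::runif(1) < 0.5) "left" else "right"
    g <- generate_trial(cfg, "sim", i, "overlap", side,
                        srt_max_ms = params$srt_max_ms)
    traces[[i]] <- as_gaze_trace(g, params)
    truth[[i]] <- g$truth
  }
  truth <- do.call(rbind, truth)
  out <- lapply(modes, function(m)
    quality_split_experiment(traces, truth, params, mode = m))
  names(out) <- modes
  attr(out, "truth") <- truth
  out
}
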