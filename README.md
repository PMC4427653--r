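# gazesrt

Automated extraction of **saccadic reaction times (SRTs)** from raw
corneal-reflection eye-tracking data, built for the two-stimulus
(gap/baseline/overlap) attention-disengagement paradigm and for
recordings from poorly cooperating participants — infants in
particular — whose gaze streams are fragmented, jittery, and riddled with
transient tracker artifacts.

## What it computes

Per trial, the pipeline combines the two eyes (validity codes 0–1
accepted, coordinates averaged, single-eye fallback), fills missing-data
gaps by continuing the last recorded coordinates forward, removes spike
artifacts with a moving median filter (default 37 samples = 123 ms at
300 Hz), and scores the SRT as the **last sample inside the central
area of interest** (the band `0.30 ≤ x ≤ 0.70` of screen width by
default) **before the gaze's first departure toward the lateral
target**, measured from second-stimulus onset. Trials in which gaze
never leaves the AOI within the 150–1000 ms window are scored *no-shift*
at the window maximum. Four post-analysis verification checks then
reject trials whose SRT cannot be trusted: recorded stimulus durations
out of bounds, an interpolated gap longer than 200 ms overlapping the
analysis period, an AOI change hidden inside a gap (*border violation*),
or insufficient fixation of the first stimulus (< 0.70 of first-phase
samples in the AOI).

Per subject and condition the package reports the count of valid /
no-shift / rejected trials, the mean SRT over valid shifts, and the
dwell-time **SRT index** over all scorable trials

$$\mathrm{SRT\ index} \;=\; \frac{1}{n}\sum_{i=1}^{n}
  \left(1 - \frac{s_{\max} - x_i}{s_{\max} - s_{\min}}\right),$$

where $x_i$ is trial *i*'s latency (a no-shift trial contributes
$x_i = s_{\max}$) and $[s_{\min}, s_{\max}]$ is the acceptance window
(defaults 150 and 1000 ms, denominator 850 ms). The index runs from 0
(every trial at the minimum latency) to 1 (no saccade on any trial) and
quantifies attentional dwell on the first stimulus.

The package also computes trial-level data-quality metrics — precision
(inter-sample RMS of consecutive valid raw samples) and robustness
(proportion of unavailable samples) — and ships a median-split
sensitivity experiment plus a fully deterministic synthetic gaze
generator with ground truth, so every stage is testable without
recording hardware.

## Worked example

```r
library(gazesrt)

# 2 subjects x 24 synthetic trials with study-like degradation
# (~18% missing data, jitter sd 0.01, 0.5 spikes/s)
ds <- generate_gaze_dataset(synth_config(), n_subjects = 2, n_trials = 24,
                            seed = 42)
paths <- write_gaze_dataset(ds, "demo")

out <- run_pipeline(list(gaze_log = paths[["gaze"]],
                         trial_table = paths[["trials"]],
                         out_dir = "demo/out"))
#> trial outcomes: valid_shift=28, no_shift=6, rejected_duration=0,
#>   rejected_interpolation=6, rejected_border=7, rejected_fixation=0,
#>   rejected_anticipatory=0, rejected_wrong_direction=1

head(out$trials[, c("trial_number", "status", "srt_ms", "longest_gap_ms")], 5)
#>   trial_number          status   srt_ms longest_gap_ms
#> 1            1     valid_shift  330.000      110.00033
#> 2            2     valid_shift  176.667      143.33333
#> 3            3        no_shift 1000.000      143.33333
#> 4            4     valid_shift  326.667      116.66733
#> 5            5 rejected_border       NA      150.00033

out$summary[, c("subject_id", "n_valid_shift", "n_no_shift", "n_rejected",
                "mean_srt_ms", "srt_index")]
#>   subject_id n_valid_shift n_no_shift n_rejected mean_srt_ms srt_index
#> 1        s01            15          3          6    375.5557 0.3877997
#> 2        s02            13          3          8    427.6925 0.4529414
```

Reading the output: trial 1's gaze left the central band toward the
target 330 ms after the lateral stimulus appeared; trial 3 never
disengaged and is scored at the 1000-ms sentinel; trial 5 had a gap
during which the gaze crossed the AOI border, so its SRT is unknowable
and the trial is rejected with that single reason. Subject s01's SRT
index of 0.39 means their gaze dwelt on the central stimulus for about
39% of the available disengagement window, averaged over the 18
scorable trials.

`run_quality_experiment(n_trials = 2000, seed = 1)` contrasts this full
pipeline with a "typical" analysis (no interpolation, no filtering, no
checks, narrower AOI margins) on identical traces: the full pipeline's
rare large errors (> 100 ms vs. ground truth) show no association with
data quality, while the typical approach's errors concentrate
significantly in low-precision and low-robustness trials.

A thin CLI over the same functions lives at `inst/cli/gazesrt.R`
(subcommands `analyze`, `simulate`, `quality-experiment`).

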