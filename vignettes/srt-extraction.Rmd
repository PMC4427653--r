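---
title: "Extracting saccadic reaction times from raw gaze data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting saccadic reaction times from raw gaze data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesrt)
```

## The measurement problem

A saccadic reaction time (SRT) task shows a central stimulus, then adds a
lateral one, and asks how long the eyes take to disengage and move. With a
corneal-reflection eye tracker the quantity is in principle trivial — find
the moment the point of gaze leaves the central region — but raw gaze
streams from poorly cooperating participants (infants, clinical groups)
are fragmented and noisy: samples drop out for tens to hundreds of
milliseconds, fixational coordinates jitter, and transient tracker
artifacts throw the reported position across the screen for a few
milliseconds. Applied naively, an area-of-interest (AOI) crossing rule on
such data produces false or badly mistimed SRTs, and the errors correlate
with data quality, confounding group and individual comparisons.

`gazesrt` implements an SRT pipeline designed to be robust to exactly
these pathologies, together with a synthetic-trace generator so every
stage can be validated against known ground truth.

## The procedure

Per trial, on samples spanning the first-stimulus onset to the end of the
analysis window:

1. **Eye combination.** Each sample keeps per-eye coordinates and a
   tracker validity code (0 best to 4 untracked). Samples whose code is in
   the accepted set (default {0, 1}) are valid; two valid eyes are
   averaged, one is used as-is, none marks the sample missing. Averaging
   with single-eye fallback is standard practice and maximizes retained
   data.
2. **Interpolation.** Missing samples are filled by continuing the last
   recorded coordinates forward until data return, regardless of gap
   duration; the bookkeeping (start, end, duration of every filled gap)
   feeds the verification checks that decide, after the fact, whether the
   filling was acceptable. A leading gap with no valid predecessor is left
   missing — there is nothing defensible to continue.
3. **Median filtering.** A moving median (default 37 samples, 123 ms at
   300 Hz) removes spike artifacts shorter than half its window without
   smearing the saccadic step the way a mean filter would; both ends of
   the period are handled by replicating the first/last available sample
   so the filter covers the whole trace. Saccades take on the order of
   100–130 ms to program, so a 123-ms window removes artifacts without
   eating real eye movements.
4. **Detection.** The central AOI is the band
   `edge_threshold <= x <= 1 - edge_threshold` (default 0.30 from each
   edge; boundary samples count as inside, one convention everywhere).
   Scanning the filtered stream from second-stimulus onset, the first
   departure from the band whose exit side matches the target defines the
   shift; the SRT is the time of the last in-AOI sample before it. No
   departure within the window scores the trial *no-shift* at the window
   maximum (default 1000 ms). Departures on the wrong side are rejected
   rather than scored — no SRT is defined for them — and latencies below
   the window minimum (default 150 ms) are rejected as anticipatory. The
   scan starts at onset, not at the minimum, precisely so anticipatory
   shifts are caught instead of silently skipped. Only x participates:
   in vertically aligned paradigms y carries no disengagement signal and
   is kept for quality metrics.
5. **Verification.** Four checks run in a fixed order — recorded-duration
   bounds for both stimulus phases, the interpolated-gap cap (default
   200 ms) over gaps overlapping the analysis period, the border-violation
   check, and the minimum-fixation requirement (default 0.70 of
   first-phase samples inside the AOI, interpolated samples counted). The
   first failure is the trial's single rejection reason; cheap structural
   checks run first so rejection accounting is deterministic and
   auditable. The border check compares the AOI region of the last valid
   raw sample before each gap with the first valid raw sample after it:
   if the region changed, a shift happened inside missing data and its
   time is unknowable. It must use raw flanks — interpolated values equal
   the pre-gap position by construction and could never reveal a shift.
6. **Aggregation.** Per subject and condition: the count of valid shifts,
   no-shift trials and rejections; the mean SRT over valid shifts only;
   and the dwell-time SRT index over all scorable trials,

   $$\mathrm{index} = \frac{1}{n}\sum_{i=1}^{n}
     \left(1 - \frac{s_{\max} - x_i}{s_{\max} - s_{\min}}\right),$$

   with a no-shift trial contributing $x_i = s_{\max}$. With the default
   150–1000 ms window the denominator is 850 ms; all-minimum latencies
   give 0 and all no-shift trials give 1. The index is affine in each
   latency and algebraically equal to
   $\mathrm{mean}\big((x_i - s_{\min})/(s_{\max} - s_{\min})\big)$; since
   anticipatory trials are rejected upstream, scorable latencies cannot
   fall below $s_{\min}$ and the index stays in $[0, 1]$ — this is
   asserted, never clamped. Groups with fewer than 3 scorable trials are
   flagged insufficient rather than dropped silently.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `valid_codes` | {0, 1} | — | tracker codes accepted as reliable |
| `filter_window_samples` | 37 | samples | median filter length (123 ms at 300 Hz) |
| `max_gap_ms` | 200 | ms | longest acceptable interpolated segment |
| `min_first_ms` / `max_first_ms` | 900 / 1100 | ms | recorded first-phase span bounds |
| `min_second_ms` | 1000 | ms | minimum recorded second-phase span |
| `min_fixation_prop` | 0.70 | — | first-phase in-AOI proportion (inclusive) |
| `srt_min_ms` / `srt_max_ms` | 150 / 1000 | ms | acceptance window for the latency |
| `edge_threshold` | 0.30 | x fraction | central AOI half-margin from each edge |
| `rate_hz` | 300 | Hz | nominal sampling rate |
| `display_span_deg` | 46 | degrees | horizontal display span for degree conversion |

All durations are user-facing milliseconds, converted once to the
microsecond timebase of the recordings. Phase and gap durations count one
nominal sample period per sample (span plus one period), so a complete
300-sample phase at 300 Hz measures exactly 1000 ms and a 3-sample gap
10 ms — this makes the 200-ms cap independent of the sampling rate. The
filter length can be given in milliseconds and is rounded to the nearest
odd sample count.

Two conventions worth stating because they decide boundary cases: the
fixation window is half-open, `[first_onset, second_onset)`, so a 1000-ms
presentation at 300 Hz contains exactly 300 samples; and every inclusive
threshold is inclusive (a fixation proportion of exactly 0.70 passes, a
gap of exactly 200 ms passes, a latency of exactly 150 ms is accepted).

## The synthetic generator

`synth_config()` / `generate_trial()` emulate the documented raw-data
pathology: Gaussian fixational jitter around screen center (plus small
independent per-eye jitter), missing-data gaps as a Poisson process with
log-normal durations, spike artifacts that jump the reported x to a fixed
coordinate for a few samples while validity stays 0, and an abrupt
x-transition at the saccade modeled as a linear ramp (default 30 ms) — a
stated simplification sufficient for AOI-crossing detection, not a
main-sequence velocity profile. The trial layout is 1000 ms of central
stimulus followed by 3000 ms with the lateral target present; true
latencies are truncated-normal (mean 400, sd 150, on [150, 1000] ms) so
the whole acceptance window is populated; 10% of trials have no shift and
5% shift the wrong way.

The default gap process (rate 2.2/s, mean length 90 ms, log-sd 0.5) was
solved analytically so that expected coverage, accounting for overlapping
gaps merging ($1 - e^{-\lambda\,\bar\ell}$), is 0.18 — the typical share
of missing samples in infant recordings.

Ground truth is defined carefully to avoid circularity: the stored
`true_srt_ms` is the closed-form instant the *noiseless* trajectory
crosses the AOI boundary, snapped to the sample grid and windowed the way
the method defines the measurement (a crossing whose first outside sample
falls past the window end is no-shift ground truth). No call to the
detector is involved. On clean traces the detector recovers this truth
exactly; the monotone step means the median filter is the identity there.

What the generator does *not* emulate: smooth pursuit, head movement,
calibration drift, pupil dynamics, two-phase (hypometric) saccades, and
vertical structure. Passing tests therefore demonstrate correctness of
the algorithms under the modeled pathologies, not performance bounds on
any particular empirical dataset.

## The data-quality sensitivity experiment

`run_quality_experiment()` reproduces, at synthetic scale, the argument
for the preprocessing and verification machinery. Each of *n* trials
draws a latent recording-quality factor $q \sim U(0,1)$ that scales
jitter sd (0.005–0.05 normalized units, roughly 0.2–2.3° on a 46°
display), gap rate (0.2–4/s) and spike rate (0–2/s) jointly. The coupling
is deliberate and matters: tracking pathologies co-occur within a
recording — a poorly tracked eye yields jittery coordinates, dropouts and
transient artifacts together — and it is this coupling that lets median
splits on the *measured* quality metrics (inter-sample RMS precision;
missing-data proportion) separate good from poor trials. An earlier
design iteration drew the pathologies independently; its spike artifacts,
the dominant error source in unfiltered analysis, were then uncorrelated
with every measured quality metric by construction and the experiment
could not exhibit the quality dependence it exists to demonstrate.

Each trial is analyzed twice on identical traces: `full` (the complete
pipeline) and `typical` (detection on the raw stream, no interpolation,
no filtering, no checks, and the AOI margin narrowed from 2.7° to 1°,
applied symmetrically as $1.7/46$ added to the edge threshold). Errors
larger than 100 ms against ground truth are tallied in a 2×2 table of
quality half × error size and tested with Pearson's chi-square
(uncorrected). Ties at the median go to the low-quality group — a fixed
rule for reproducibility. At 2000 trials the full pipeline shows rare
large errors with no quality association, while the typical approach
shows a strong association for both metrics: gaps swallow crossings
(robustness) and unfiltered spikes cross the narrowed border
(precision) — mechanically the same failure modes the verification
checks and the median filter were designed against.

The quality metrics themselves: precision is the RMS of Euclidean
distances between consecutive valid raw samples (pairs spanning gaps
excluded) — a deliberately simple inter-sample dispersion statistic whose
properties (translation invariance, linear scaling, large-sample value
$2\sigma$ under isotropic white jitter of sd $\sigma$ per axis) are
pinned by the package's own tests; robustness is the proportion of
unavailable samples in the trial excerpt. Excerpts run from trial start
to the detected saccade, or over the first 2000 ms when no shift was
detected. Degree conversions use the linear small-angle mapping
`degrees = normalized units × display span`.

## Numerical and degenerate-input choices

- Time is integer-rounded microseconds internally; all comparisons are
  on that grid. Detection is invariant to the absolute time origin.
- The median filter requires an odd window not longer than twice the
  trace; its inner kernel is an exact windowed median (end-replication
  padding), verified against a naive per-index oracle.
- A trace with zero valid samples is passed through flagged, and every
  check that needs data (durations, fixation) fails it; an empty analysis
  window yields a duration rejection.
- A degenerate 2×2 table (an empty margin) yields an absent chi-square
  with a reason, never a fabricated statistic.
- Writers round numeric fields to 3 decimals and encode missing values as
  empty cells — no sentinel numerics that could contaminate downstream
  means.

## Problem sizes used in the validation suite

The test suite validates the median filter and the detector against
brute-force re-implementations on 1000 randomized traces each, checks
parameter recovery on 500 clean and 500 study-like degraded trials
(expecting ≥ 95% of scorable trials within 100 ms of truth under
degradation), and runs the sensitivity experiment at 2000 trials. These
sizes give stable proportions while keeping the whole suite under a
minute on one CPU; the experiment's qualitative contrast is already
unambiguous at a few hundred trials.

## Known limitations

- The exit-side rule scores only the first departure; two-phase saccades
  (a small movement near the border followed by the real shift) can be
  scored at the first movement, the same ambiguity manual coding faces.
- Forward continuation is a stance, not an imputation: long gaps are
  rejected, never modeled.
- Precision here is an inter-sample statistic; it does not measure
  accuracy (calibration offset), which the pipeline deliberately does not
  depend on.
- The AOI geometry is one horizontal band; paradigms with vertical
  targets or more than two lateral positions are out of scope.
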