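---
title: "Few-shot gait partitioning: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot gait partitioning: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpartition)
```

## The problem and the model

Clinical gait analysis partitions walking into stance (foot on ground)
and swing (foot in air), separated by the foot-contact and foot-off
events. The laboratory gold standard reads these events off force plates
(vertical ground reaction force crossing 10 N), but plates capture only a
couple of steps per trial and severely impaired gait often defeats them.
Wearable accelerometers capture every step, but population-trained event
detectors fail on patients who walk very unlike the training cohort.

`gaitpartition` implements a few-shot alternative. The supervision unit
is a *hint*: one user-annotated swing interval on one channel. The hint
becomes a template; fuzzy time-domain template matching finds every other
swing; and an escalation rule turns the human back on only when the
result is demonstrably not good enough. The pipeline is:

1. **Condition** the channel: FFT hard low-pass, then the
   Kolmogorov–Zurbenko (KZ) filter — `k` iterated applications of a
   centred moving average of odd length `m`, whose effective kernel is the
   `k`-fold boxcar convolution (approaching a Gaussian).
2. **Quantize** signal and template into `L` uniform amplitude bins over
   the 1st–99th percentile of the signal (outliers clip into the end
   bins).
3. **Match**: slide the template at every sample offset and a grid of
   length scales; score each window with the fuzzy Hamming distance
   `mean(min(|a_i - b_i|, 2) / 2)`, which forgives one-bin wobble
   (cost ½) and saturates at two bins. Windows under the acceptance
   threshold become candidates.
4. **Select** non-overlapping cycles greedily, best distance first, ties
   to the earlier start, with each interval dilated by a refractory gap
   before the overlap test — two swings of one foot cannot be closer than
   a stance phase.
5. **Refine**: the template becomes the pointwise median of the matched
   instances resampled to their median length (robust to one bad match),
   and steps 3–5 repeat until the selected boundaries move by less than
   one sample, at most 20 iterations. On every fixture in the test suite
   the loop converges in far fewer.
6. **Extract events**: each swing interval yields a foot-off at its start
   and a foot-contact at its end.
7. **Score and escalate**: predicted events are matched to the nearest
   same-type truth event within 0.5 s; if any absolute error exceeds
   0.060 s (or nothing matched at all), the recording is absorbed into
   the training set, one of its true swing intervals becomes a new hint,
   and the remaining recordings are re-partitioned.

An unsupervised first-pass segmenter (a diagonal-covariance Gaussian
hidden Markov model fit by EM on per-sample features: smoothed value,
first difference, windowed RMS) is provided to propose initial state
boundaries a user can annotate against. It is advisory: the final
partition always comes from the hint matcher. The EM and Viterbi routines
are written in the package because no HMM library is among its
dependencies; they are validated against simulated chains with known
state paths.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `kz_m`, `kz_k` | 5, 3 | samples, – | At 100 Hz, kernel support ~130 ms: removes sample noise, keeps the ~0.4 s swing transients. |
| `fft_cutoff_hz` | 15 | Hz | Gait accelerometer content sits below ~10 Hz; 15 Hz leaves headroom. |
| `levels` | 16 | bins | Coarse enough that conditioned noise rarely moves a sample one bin; fine enough to separate burst from baseline. |
| `accept_threshold` | 0.25 | – | Calibrated on synthetic fixtures: true swings score ≲ 0.2 under default noise, stance windows ≳ 0.4. |
| `length_scales` | 0.80–1.20 by 0.05 | – | Span covers step-time variability across trials; see below for the step size. |
| `refractory_s` | 0.10 | s | Shorter than any stance phase, longer than boundary jitter. |
| `threshold_s` | 0.060 | s | The escalation bound: the error level at which a partition stops being clinically acceptable. |
| `emg_band_hz`, `envelope_cutoff_hz` | 20–450, 10 | Hz | Standard surface-EMG conditioning; both filters fourth-order Butterworth, applied forward–backward. |
| Force-plate `threshold_n`, `debounce_s` | 10 N, 0.05 s | | The 10 N rule at sample resolution; the debounce makes it well-defined on plates that chatter around the threshold. |

**Why a 5% scale step.** The scale grid is the only mechanism that adapts
template length to step-time variability. The heel-strike transient is
sharp (tens of milliseconds); with a 10% grid the best available window
can misalign it by up to 5% of the swing (~20 ms), which pushes the fuzzy
distance of well-formed swings past the acceptance threshold — on the
default 20-step fixture a 10% grid recovers only 15 of 20 swings, the 5%
grid 18–20 across seeds, with identical timing accuracy. Halving the step
again buys one further cycle at double the cost, so 5% is the default.

**Zero-phase filtering everywhere.** Event *times* are the product being
validated; causal filters would shift every boundary by the group delay.
Forward–backward application cancels phase at the price of acausality,
which batch analysis can afford. The KZ filter reflect-pads each
iteration so endpoints are not dragged toward zero, which would bias the
first and last events of a trial.

**Cross-recording templates.** A hint annotated on one recording must
partition others (that is the point of the reinforcement loop), but two
recordings need not share an amplitude scale. Templates therefore store
the conditioned real-valued curve; at match time the *target* recording's
percentile bins code both the target and the resampled template. Within
one recording this reduces to the ordinary shared quantization.

**Polarity.** Laboratory accelerometer signals flip sign with walking
direction. With polarity `auto` (the default) each template is matched
against the signal and its negation and the variant with the lower mean
selected distance wins; `as_is` and `inverted` pin the choice. Because
the percentile bins are symmetric under negation, a globally flipped
recording yields bit-identical cycles.

## The synthetic generator

Real patient recordings are not distributable, so the package carries a
generator whose output is consistent *by construction* with an exactly
known event timeline: cycle durations jitter multiplicatively
(`step_time_cv`, clipped at 3 sigma) around `1/cadence_hz`, each shared by
both sides so the half-cycle interleaving never drifts; stance occupies
`stance_fraction` of each cycle. Channels:

* foot accelerometer (100 Hz): quiet stance baseline, biphasic swing
  burst — push-off and heel-strike Gaussian transients, amplitude ratio
  2:3 with opposite signs — plus white noise (`noise_sd`, default
  0.5 m/s²);
* per-foot vertical GRF (1000 Hz): zero in swing, a double-bump
  body-weight curve in stance that never dips below 15 N, so the 10 N
  detector reproduces the commanded events to one sample;
* malleolus/pelvis markers (100 Hz): feet advance one stride per cycle
  such that the inter-malleolus distance at each contact equals
  `step_length_m`; the pelvis advances at `walking_speed_mps`
  (by default the value implied by the step geometry,
  `2 * step_length_m * cadence_hz`);
* gastrocnemius-like EMG (1000 Hz): noise bursts gated to late stance.

Each side's timeline opens with a lead swing and closes in stance, so a
spec with `n_steps` per side holds exactly `n_steps` complete swings and
`2 * n_steps` countable steps. What the generator does **not** emulate:
pathological asymmetries, turning, marker occlusion and soft-tissue
artefact, non-stationary noise, and real morphological variety in the
swing burst. Passing tests therefore demonstrate the machinery —
conditioning, matching, selection, escalation arithmetic — not clinical
performance on any real population; the escalation bound, not the
published patient-cohort error statistics, is the quantity the synthetic
cohort can meaningfully reproduce.

## Numerical choices and degenerate inputs

* Times are seconds everywhere; indices are 0-based internally; intervals
  are half-open `[start, end)` at sample resolution — unambiguous across
  the mixed 100/500/1000 Hz rates.
* Traces keep native rates; cross-rate comparisons happen in seconds.
  Missing samples are rejected at ingestion (no imputation rule would be
  defensible), with the offending row and column named.
* A constant trace quantizes to a single occupied bin (edges spread ±0.5
  around the value); a constant feature matrix short-circuits the HMM to
  one state rather than letting EM chase zero variances (which are also
  floored at 1e-8).
* EM: 10 seeded k-means restarts, best log-likelihood kept, relative
  tolerance 1e-4, at most 200 iterations; the per-iteration
  log-likelihood trace is stored and asserted non-decreasing.
* Cycle selection ties (equal distance) break on the earlier start, so
  results are deterministic; the greedy result is always feasible and
  maximal (no rejected candidate still fits), verified against subset
  enumeration on small candidate sets.
* Step counting finds prominent extrema of the left-minus-right ankle
  distance. Prominence uses an open-side convention — a side with no
  strictly higher sample is ignored — so the last step's plateau, which
  runs into the end of the trial, keeps its prominence; a level gate
  (halfway between the median and the 98th percentile) rejects the
  standing-still plateau at the start, which is a shoulder, not a step.
* Stream synchronization maximizes normalized cross-correlation over
  lags, then refines the peak by parabolic interpolation, rather than
  pairing discrete peaks: one global optimum, no pairing heuristics.

## Problem sizes

The test suite and the acceptance script run on recordings of ~20 steps
per side (~25 s multimodal data) and cohorts of 10 subjects spanning
cadence 0.7–1.2 steps/s and stance fraction 0.55–0.65 — the spread of a
small clinical validation cohort, and large enough that the reinforcement
loop exercises both its escalation and its termination paths. The full
suite runs in about a minute on one core.

## Known limitations

* Matching runs on one accelerometer channel; EMG is partitioned by the
  resulting events rather than matched directly.
* The matcher assumes the hinted morphology recurs; gait that changes
  character mid-trial (freezing, turning) will escalate rather than
  adapt within a trial.
* Scale quantization bounds how well template length tracks step-time
  variability; beyond ±20% of the hint length a new hint is the intended
  remedy.
* The unsupervised segmenter labels statistical regimes, not named gait
  phases; it seeds annotation and nothing else.
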