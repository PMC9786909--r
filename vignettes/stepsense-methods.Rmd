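---
title: "Counting steps from wrist accelerometry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting steps from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepsense)
```

## The measurement problem

Steps per day is the activity metric people actually understand, but the
wrist — where research and consumer devices live — is a hostile place to
count them. The arm swings with gait, so each step does leave an
acceleration signature; it also washes dishes, types, and gestures, which
leaves very similar signatures that are not steps. A wrist step counter is
therefore a peak detector followed by a stack of plausibility filters, and
its validity question ("how close are its daily totals to a trusted
reference device?") is a method-agreement question. This package implements
all three layers: the counter, the stepping metrics, and the agreement
statistics, together with a signal simulator that provides exact ground
truth.

## The step-count model

The detector consumes the per-sample Euclidean norm of the three axes with
gravity retained, so a resting wrist sits near 1 g and the magnitude
thresholds (1.2/1.25 g) are above-gravity values. Processing is staged, and
each stage only removes peaks:

| stage | parameter (unit) | `verisense1` | `verisense2` |
|---|---|---:|---:|
| candidate peaks | `peak_win_samples` (samples) | 3 | 4 |
| magnitude | `magnitude_threshold_g` (g) | 1.2 | 1.25 |
| periodicity | `min/max_period_samples` (samples) | 5–15 | 4–20 |
| similarity | `similarity_threshold_g` (g) | −0.5 | −1.0 |
| continuity | window / count (samples, windows) | 4 / 4 | 4 / 4 |
| motion recognition | `variance_threshold_g2` (g²) | 0.001 | 0.01 |

A candidate is a *strict* local maximum over a symmetric ±k window.
Periodicity requires the sample gap to the previously retained peak to lie
in a closed interval; similarity bounds the height difference of
consecutive peaks (the threshold is conventionally printed negative: the
test is `−|Δh| ≥ threshold`); continuity demands that the signal around the
peak is genuinely in motion, measured as tumbling-window variance.

### The operating rate

The sample-unit thresholds only mean something at a stated rate, and the
convention here is **15 Hz**, with the input magnitude linearly resampled
before detection. At 15 Hz the periodicity windows [5, 15] and [4, 20]
samples correspond to step intervals of 0.27–1.33 s, i.e. roughly 45–225
steps/min — exactly the physiological band — which is why that rate is
frozen as the default (`algorithm_rate_hz`). Devices record faster
(typically 100 Hz) and are downsampled; recordings already at 15 Hz pass
through untouched.

### Frozen conventions

Several details are under-determined by the algorithm's published
description; each is fixed once here, for bit-reproducibility:

* **Filter order** is magnitude → periodicity → similarity → continuity.
  The magnitude test is a property of the peak itself and naturally runs
  first; the other three are listed in their assessment order.
* **Plateaus produce no peak.** Strict inequality on both sides avoids
  double-counting flat-topped oscillations.
* **Periodicity chains measure gaps to the previously *retained* peak**,
  not to the previous candidate. A run's first peak is kept only once a
  compliant gap follows it; an isolated peak is never a step (a single
  event cannot be periodic). A too-small gap drops the intruding peak and
  leaves the chain anchor in place; a too-large gap starts a new run.
* **Window variance is the population variance** (divisor *n*).
* **Continuity counts the `count` full windows on each side of the peak's
  own window** (2 × count windows, own window excluded); windows past
  either end of the recording count as "not in motion". This centred
  convention is symmetric and makes the lone-spike case (high own-window
  variance, quiet surroundings) fail cleanly.

These conventions are shared by `count_steps()` and by the deliberately
naive loop-based oracle `naive_count_steps()`, which re-derives them in
independent code; the test suite holds the two equal across hundreds of
random and simulated signals.

## Epochs, cadence, MVPA

Step events are aggregated into half-open epochs `[t, t + 5 s)` anchored at
the start of the requested span (midnight, in the daily pipeline). Epoch
cadence is `steps × 60 / epoch_length`, so with the default 5-s epochs the
MVPA rule "cadence ≥ 100 steps/min" has an exact integer boundary: 9 steps
(108 steps/min) is MVPA, 8 steps (96 steps/min) is not. Classification is
per-epoch and instantaneous — no bout smoothing — because the daily MVPA
step total is defined directly from per-epoch cadence. Day validity (24-h
wear on both devices, calibration QC) enters as externally supplied flags:
non-wear detection and autocalibration live upstream of this package and
are deliberately out of scope.

## Agreement statistics

For paired daily totals (test − reference differences $d_i$, $n$ pairs):

* mean bias $\bar d$ with CI $\bar d \pm t_{n-1,0.975}\, s_d/\sqrt n$;
* 95% limits of agreement $\bar d \pm 1.96\, s_d$ with $s_d$ the sample SD
  (divisor $n-1$); the 1.96 multiplier is fixed by convention;
* proportional bias: OLS of $d_i$ on the pair mean $(t_i + r_i)/2$;
  "no proportional bias" iff the slope CI covers zero;
* MAPE $= \overline{|d_i|/r_i} \times 100$ (requires $r_i > 0$);
* percent bias $= \bar d / \bar r \times 100$.

Display rounding follows the reporting convention of validation studies in
this field: biases to whole steps, percentages to one decimal, halves away
from zero (`round_half_up()`). Zero-variance differences collapse the LoA
to a point and set a `degenerate` flag rather than failing.

Agreement can be computed per valid day (default) or on per-participant
means; the pairing unit genuinely changes the numbers when participants
contribute unequal day counts, which is why both modes exist and the choice
is recorded in the output.

## Grid tuning

`tune_parameters()` evaluates the full Cartesian product of candidate
threshold values, running the counter on every training recording for every
combination (the resampled magnitude is computed once per recording, so a
1152-combination grid over three one-minute recordings takes seconds).
"Balanced performance between under- and over-estimation" is formalized as
a lexicographic objective: minimize |mean bias|, break ties by
|#overestimated − #underestimated| recordings, break remaining ties by grid
order. The rule is deliberately simple and totally ordered so the selection
is reproducible; combinations with an empty periodicity interval are
skipped and logged.

## The synthetic signal model

`simulate_bout()` builds a magnitude envelope of 1 g baseline plus one
raised-cosine pulse per step (half-width 0.12 s, peak `1 + swing
amplitude`), plus a broad raised-cosine *trough* below baseline at
half-period (depth `harmonic_ratio ×` amplitude, half-width a quarter
period). The trough is the model's second-harmonic content: physically it
is the unloading phase of the arm swing, and mechanically it keeps the
signal in motion between impact peaks so that the continuity filter sees
gait the way it sees real gait. Because it is a minimum it can never create
a candidate peak. The envelope is distributed over the axes by a fixed unit
vector (so the norm reproduces it exactly), then Gaussian axis noise is
added and values are clipped to the device range.

Defaults, chosen once as field-realistic and then frozen:

* wrist device 100 Hz, ±8 g; reference device modelled only through its
  daily totals (20 Hz, ±2 g hardware is irrelevant to those);
* swing amplitude 0.6 g, jitter SD 0.01 s, `harmonic_ratio` 0.7, noise SD
  0.01 g (≈10 mg sensor noise);
* artefact bursts 20/h at up to 1.4 g: 3–8 aperiodic peaks with random
  spacing (0.15–0.9 s) and width, which mostly — not always — fail the
  periodicity and similarity tests, exactly like real hand-use artefacts;
* the pulse half-width (0.12 s) was set so that after 15 Hz resampling the
  sampled peak keeps ≥ ~80% of its nominal height up to 140 steps/min: a
  0.4 g swing must remain detectable under the 1.25 g threshold, since
  clean-gait detectability across 90–140 steps/min at 0.4–1.0 g is part of
  the package's acceptance contract. The trough depth 0.7 was chosen in the
  same pre-freeze design pass so that window variances during 0.4 g gait
  sit clearly above the 0.01 g² motion threshold.

`simulate_reference_device()` converts exact ground truth into what a
thigh-worn comparator would log: steps from bouts below a cadence floor
(default 40 steps/min — the comparator's documented slow-walking blind
spot) are never detected, and remaining steps are missed independently with
a small probability (default 0.02).

**What the simulator does not emulate** — and therefore what a green test
does *not* establish: real gait variability (asymmetry, fatigue drift,
surface changes), posture transitions, device orientation changes, sensor
calibration error, and the full diversity of free-living artefacts. Green
recovery tests establish that the implementation applies the published
thresholds correctly to signals with known structure; they are not a
free-living validity claim. The headline free-living biases of the
validation literature were measured on hundreds of participants' private
recordings and cannot be regenerated from synthetic data; the acceptance
script instead reproduces the printed between-group arithmetic exactly.

## Numerical choices and degenerate inputs

* Times are naive local clock times held as UTC POSIXct, so no DST
  arithmetic can reorder samples; day boundaries are plain midnights.
* Raw CSV values are written at 6 decimal places of g and round-trip
  exactly at that precision; sampling rate is taken from the metadata line,
  cross-checked against the first timestamp gap (>1% disagreement is an
  error), and near-integer inferred rates are snapped to the integer
  (timestamp parsing carries ~1 µs noise).
* Resampling never extrapolates past the last input sample and keeps
  `n/rate` duration no longer than the input's.
* ENMO truncates negatives per sample *before* epoch averaging, and
  trailing partial epochs are discarded, never padded.
* Recordings shorter than one continuity window (or ≤ 2k samples) yield
  zero steps with a warning, not an error; empty recordings are errors.
* Splitting a recording at an epoch boundary and summing the two counts
  can differ from whole-recording counting by up to 2 steps per split point
  (edge exclusion of the peak window); the test suite pins this bound.

## Known limitations

* The periodicity/similarity chain rules are one reasonable reading of a
  prose description; other implementations may break ties differently, so
  step-for-step equality with third-party code is not guaranteed (daily
  totals on clean gait agree to within a few steps).
* The continuity centring convention is a dialect choice (flanking windows,
  own window excluded); it is documented and frozen but not the only
  defensible one.
* MAPE is undefined for zero reference days; such pairs are an error by
  design rather than being silently dropped.
* The tuner is exhaustive, not clever: grids beyond ~10⁴ combinations ×
  long recordings will be slow, which matches its intended use (small,
  explicit threshold grids).
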