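---
title: "Methods: windowed psychophysiology of sensor-instrumented work shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed psychophysiology of sensor-instrumented work shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftsense)
```

## The problem

Wrist-worn multichannel biosensors make it practical to observe a worker's
autonomic state continuously across a duty shift. Electrodermal activity
(EDA) — skin conductance in microsiemens, driven purely by sympathetic
activation — is the primary stress index; skin temperature, 3-axis
acceleration, blood volume pulse (BVP) and the interbeat intervals (IBI)
derived from it complete the channel set. On its own the biometric record
says *that* arousal changed, not *why*. For patrol officers, two agency
systems supply the missing context: the computer-aided dispatch (CAD) log,
which timestamps every phase of every call for service, and the automated
vehicle locator (AVL), which pings the patrol vehicle's position every few
seconds while moving and every half minute or so at rest.

`shiftsense` turns one officer-shift of these three sources into a single
analysis-ready table — 19 metrics on non-overlapping 20-second windows —
and fits mixed-model trajectories to the result. Because no officer data
are publicly deposited, the package also contains a first-class synthetic
generator that emulates all three sources with known ground truth, and the
test suite exercises every stage against that truth.

## Signal processing

**EDA decomposition.** The 4 Hz conductance stream is split into a slow
*baseline* (tonic level, roughly 0–0.04 Hz) and a *bandpass* fluctuation
signal (phasic activity, roughly 0.04–0.4 Hz). Both are third-order
polynomial (Savitzky–Golay) smoothers: a 101-point window for the baseline
and an 11-point window applied to the residual after baseline removal.
The nominal 100- and 10-point window lengths are realized as the nearest
odd integers, which a centered polynomial filter requires; the resulting
cutoffs remain at approximately 0.04 and 0.4 Hz. Polynomial smoothers pass
constants and low-degree trends exactly — the property the tests pin down —
and the measured frequency response at 0.2 Hz (mid-band for phasic
activity) is a gain of about 0.93 into the bandpass and 0.04 into the
baseline. Edges use reflect padding so every sample is produced by the
central filter row; the first and last half-window of each band are still
edge-influenced and worth caution.

**Activity.** The three acceleration axes collapse to the per-sample
Euclidean norm, which is then band-passed to 0.1–7 Hz with a fifth-order
Butterworth filter run forward and backward (zero phase, effective order
ten). The high-pass corner removes gravity, so a motionless wrist scores
near zero. Activity *counts* are the sums of absolute filtered values over
1-second epochs, and each 20-second window reports the mean of its twenty
counts.

**Windowed EDA metrics.** Per window the package reports the mean baseline
level; its difference and z-score against the 60 windows spanning 20 min
20 s to 20 s before the window start; the least-squares baseline slope over
the window and over the 120 seconds centered on the window midpoint; the
RMS of the bandpass signal with the same difference/z normalization; and
counts plus mean heights of bandpass peaks at two thresholds (0.15 and
0.02 microsiemens, minimum 1 s separation). Conventions worth stating
because each had a genuinely open reading:

* *Normalization history.* "20:20 to 0:20 previous" is taken literally as
  the 60 windows whose spans tile that interval — indices `k-61 … k-2`
  relative to the current window `k`. The first 61 windows of a session
  therefore have missing difference and z metrics, and a zero-variance
  history yields a missing z-score rather than an infinity.
* *120-second slope.* "The current point" is the window midpoint; the span
  is truncated at session edges and the slope reported only when at least
  half the span's samples exist.
* *Peaks.* A peak's height is the bandpass sample value at the local
  maximum (not its prominence, since the thresholds are absolute
  conductance values). Among maxima closer than the minimum separation the
  larger survives, ties resolving to the earlier; a zero-peak window has a
  missing mean height (the mean of an empty set), not zero.
* *Midnight.* Elapsed-time-from-midnight uses a configurable fixed UTC
  offset, default 0; night shifts cross midnight and the metric resets
  there by construction.

**Bad data.** The device vendor's proprietary quality algorithm is not
published, so the package ships its own pluggable surrogate: a 5-second
interval is bad when EDA leaves [0.01, 100] microsiemens, jumps more than
5 microsiemens between adjacent samples, or skin temperature leaves
[20, 45] degrees C. Each window reports the sum of its four interval flags:
4, 2, 0, −2, −4 for 100%, 75%, 50%, 25%, 0% good. All thresholds are
arguments.

**IBI quality.** Heart-rate-variability analysis is deliberately deferred;
what the package quantifies is whether the interbeat record could support
it. A beat closing interval `d` at offset `o` covers `[o − d, o]`; the
record gaps wherever consecutive covered spans fail to tile within a
0.25-second tolerance. Reported are the longest gap-free segment, the mean
and SD of gap lengths, and a per-window rating mirroring the bad-data
scale: four 5-second intervals per window, each good when beat coverage
reaches 80%. The tolerance and coverage fraction are configurable — "valid
data" had no published operational definition, so these are documented
conventions.

## Event coding and fusion

Every second of the shift is coded by call phase: 0 unassigned, 0.5
throughout a canceled call's dispatched span, 1.0 dispatch to first
arrival, 2.0 first arrival until the next lifecycle event (and from a
second arrival to clearing when no transport occurs), 2.5 second arrival
to transport, 3.0 transport to cleared. Three conventions were open and
are fixed here: unassigned seconds code 0; the window event code is the
mode of its 20 seconds with ties broken toward the larger (deeper) phase;
and a canceled call's span runs from dispatch to a `canceled_time` field —
real dispatch systems close canceled calls with a timestamp, but the
lifecycle schema here has no cleared time for them, so the CAD table
carries that extra column.

Fusion is a strict left join onto the window grid: row count never
changes. Windows whose event code exceeds zero inherit the dominating
call's id, type and priority; an `allocated` flag marks windows where
in-call seconds hold a majority; vehicle coordinates come from the nearest
AVL ping within 30 seconds of the window midpoint (the slowest expected
ping cadence), and are missing beyond that tolerance.

## The synthetic generator

The generator is the package's stand-in for field data and defines the
conditions every end-to-end test runs under. Defaults describe a 12-hour
patrol shift and were chosen once, on physiological and operational
grounds, not tuned to any test: tonic EDA 2 microsiemens drifting upward
0.1 per hour (sweat accumulation), measurement noise SD 0.01, discrete
skin-conductance responses as a bi-exponential kernel (rise 0.75 s, decay
3 s, unit-peak normalized, log-normal amplitudes around 0.3 microsiemens)
arriving as a Poisson process at 1/min off-call, 2/min during low-stress
calls and 5/min during high-stress calls; wrist temperature 33 °C with a
slow oscillation; gravity-plus-noise acceleration with about six movement
bouts per hour; heart period 0.8 s shortening to 0.65 s under high stress,
2% beat-to-beat jitter; about one sensor-dropout gap per hour (20–60 s)
deleted from the beat record; AVL pings every 3 s en route and every 30 s
otherwise, on planar xy coordinates (the analysis uses location only for
linkage, so no geodesy). Streams cover `[start, start + duration)` — the
last sample sits one sample period before the nominal end — EDA is clipped
below at 0.001 microsiemens (conductance is positive), and every random
draw descends from the single config seed, making output byte-identical
across runs.

Injected structure is logged as ground truth (SCR event times and
amplitudes, IBI gap schedule, movement bouts) so downstream stages can be
tested for *recovery*, not just shape. What the generator does not emulate:
realistic BVP morphology, motion artifacts in EDA, electrode detachment,
road networks, or officer behavior. Passing tests therefore demonstrate
that the pipeline computes its stated quantities correctly and recovers
planted structure — not that the surrogate quality rule or the peak
thresholds are optimal for any particular field deployment.

## The trajectory model

The modeling stage estimates, for a chosen window metric as outcome,

$$Y_{it} = \beta_0 + u_{0i} + \beta_1\,\mathrm{time} + u_{1i}\,\mathrm{time}
  + \beta_2\,\mathrm{Intx}_{it} + \beta_3\,(\mathrm{Intx}\times\mathrm{time})_{it} + e_{it},$$

with officers `i` at level 2 contributing normal random intercepts and
slopes, time in hours coded zero at each shift start, any within-shift
condition indicator (call phase, intervention) as fixed effects, and a
residual that may be independent, first-order autoregressive, or
banded-correlated. Estimation choices:

* **REML for reporting, ML for comparison.** Full maximum likelihood
  underestimates variance components in small level-2 samples; REML is the
  default, and `compare_models()` refuses anything but ML fits because
  REML likelihoods are not comparable across fixed-effect structures.
* **Small-sample inference.** With two or three officers, normal-theory
  Wald tests are anticonservative. Satterthwaite degrees of freedom are the
  default (available at any sample size); Kenward–Roger is offered where
  the machinery supports it — independent errors — and its cost grows
  quadratically in the number of observations, so it is practical at
  desk scales, not over full multi-shift series. Every fit records the
  method actually used. The tests verify the corrected test is never more
  liberal than the uncorrected z test, replicate by replicate.
* **Correlated errors.** AR(1) uses the classical corAR1 structure within
  officer. The banded ("Toeplitz") option is realized as a moving-average
  correlation of order `bands`: its autocorrelation is exactly zero beyond
  the band, which is the Toeplitz banding structure, with the band values
  constrained to an MA-representable set — no installed engine fits a
  free-band Toeplitz, and the constrained family preserves the modeling
  intent (short-memory residual correlation). These engines provide
  between-within residual degrees of freedom, recorded as such.
* **Missing windows** (bad data, the 61-window normalization run-in) are
  dropped listwise with a logged count before fitting.
* **BLUPs** of each officer's `(u0i, u1i)` are exposed via `blup()`.

`phase_contrast()` packages the common question — does a window metric
differ between classes of calls? — as descriptive means/SDs per class plus
a model-based contrast with the class as a fixed effect and a random
officer intercept when two or more officers are present. Because the tonic
level drifts over a shift, call phases are confounded with time-of-shift;
the `covariates` argument admits time (or any other column) as a
statistical control fixed effect, and the end-to-end checks use it. With
degenerate (zero-variance) input the contrast is reported as exactly zero
with p = 1 rather than NaN.

## Numerical choices and problem sizes

Window arithmetic uses `floor(duration / 20)` complete windows; trailing
partial windows are dropped everywhere (features, event codes, flags) so
all per-window vectors align. The simulation-based checks in the test
suite run at sizes chosen to estimate their quantities stably: oracle
equivalence on 10–30-minute sessions, the interval-coverage and bias study
at 100 replicates of 3 officers × 2160 windows (one 12-hour shift each) —
the scale named in the package's own recovery example — the REML/ML
agreement check at 50,000 rows, the AR(1)-preference and type-I-error
properties at 15–200 smaller replicates. The end-to-end stress-contrast
check runs three full 12-hour synthetic shifts through generation,
extraction, fusion and contrast.

## Known limitations

The bad-data rule is a surrogate, not the vendor's algorithm; peak
detection reports sample-valued heights (no sub-sample interpolation);
window-local peak detection can miss a response whose maximum falls
exactly on a window boundary; EDA decomposition by smoothing is not a
deconvolution to sudomotor driver functions, so overlapping responses
merge; the free-band Toeplitz structure is approximated by its MA-banded
subfamily; Kenward–Roger inference is impractical over full-shift series;
and the canceled-call span convention (dispatch to cancellation) is a
documented choice the underlying lifecycle schema leaves open.
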