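# shiftsense

Contextualized psychophysiology of sensor-instrumented work shifts.

Wrist-worn multichannel biosensors record a worker's autonomic state
continuously — electrodermal activity (EDA, skin conductance in
microsiemens, a pure index of sympathetic arousal), skin temperature,
3-axis acceleration, blood volume pulse and the interbeat intervals
derived from it. For patrol officers, two agency systems supply the
operational context the biometric record lacks: the computer-aided
dispatch (CAD) log, which timestamps every phase of every call for
service, and automated vehicle locator (AVL) position pings. `shiftsense`
fuses the three sources into a single analysis-ready table — **19 metrics
on non-overlapping 20-second windows** — and fits mixed-model trajectories
to the result.

The pipeline:

1. **Ingestion** — per-channel CSV session directories (EDA/TEMP 4 Hz,
   ACC 32 Hz, BVP 64 Hz, irregular IBI), CAD event-log CSV, AVL ping CSV
   (`read_e4_session()`, `read_cad_log()`, `read_avl_track()`).
2. **Feature extraction** (`extract_metrics()`) — tonic/phasic EDA
   decomposition by third-order polynomial smoothing (101- and 11-point
   windows, cutoffs ≈ 0.04 / 0.4 Hz); per-window mean EDA level and
   bandpass RMS, each normalized by a difference and a z-score against the
   preceding 20 minutes of windows; baseline slopes over 20 s and 120 s;
   skin-conductance-response peak counts and mean heights at 0.15 and 0.02
   microsiemen thresholds (≥ 1 s apart); activity counts from the
   0.1–7 Hz zero-phase Butterworth-filtered acceleration norm; mean
   temperature; a five-level bad-data rating; time bookkeeping.
3. **Event coding and fusion** (`event_assignment_timeline()`, `fuse()`) —
   every second coded by call phase (0.5 canceled, 1.0 dispatch→arrive,
   2.0 on scene, 2.5 arrive-2→transport, 3.0 transport→cleared), windowed
   by mode; call id/type/priority and nearest-ping coordinates joined onto
   the window grid.
4. **IBI quality** (`ibi_gap_stats()`, `ibi_window_quality()`) — longest
   valid segment, gap statistics, and per-window ratings on the bad-data
   scale.
5. **Modeling** (`fit_mmta()`) — the two-level trajectory model

   *Y*<sub>it</sub> = β₀ + u₀ᵢ + β₁ time + u₁ᵢ time + β₂ Intx<sub>it</sub> + β₃ (Intx×time)<sub>it</sub> + e<sub>it</sub>

   with per-officer random intercepts and slopes, REML estimation for
   reporting, ML for `compare_models()`, Satterthwaite or Kenward–Roger
   degrees of freedom, and independent / AR(1) / banded error structures.
   `phase_contrast()` compares a window metric between classes of calls
   with optional statistical controls; `blup()` exposes per-officer
   random-effect predictions.

Because no field data are deposited, the package includes a first-class
synthetic generator (`synth_session()`, `synth_cad_log()`,
`synth_avl_track()`) producing all three sources with stress-linked
structure and logged ground truth, so every stage is testable end to end.

## Worked example

One synthetic 12-hour shift with six calls (two of them high-stress),
extracted, fused, and tested for a call-phase contrast:

```r
library(shiftsense)

cfg   <- synth_config(seed = 7, shift_hours = 12)
calls <- synth_calls(cfg, n_calls = 6, p_high = 1/3, p_canceled = 0)
cfg   <- synth_config(seed = 7, shift_hours = 12, calls = calls)

session <- synth_session(cfg)
cad     <- synth_cad_log(cfg)
avl     <- synth_avl_track(cfg, cad)
session
#> <sensor_session> start 1464771600.000, duration 43200.0 s
#>   eda   172800 samples @ 4 Hz   temp  172800 samples @ 4 Hz
#>   acc  1382400 samples @ 32 Hz  bvp  2764800 samples @ 64 Hz
#>   ibi    54366 beats

timeline <- event_assignment_timeline(
  cad, c(cfg$shift_start, cfg$shift_start + 12 * 3600))
windows <- extract_metrics(session, timeline)   # 2160 x 19
fused   <- fuse(windows, cad, avl)

round(subset(as.data.frame(fused), allocated)[1,
      c("event_code", "avg_eda_level", "rms_eda", "n_peaks_low",
        "priority")], 4)
#>    event_code avg_eda_level rms_eda n_peaks_low priority
#> 43          1        2.0524  0.0388           2        3
```

The first allocated window sits in the dispatch-to-arrival phase
(event code 1.0) of a priority-3 call: tonic level 2.05 microsiemens, a
modest phasic RMS, two low-threshold skin-conductance responses.

```r
ibi_gap_stats(session$ibi, session_duration(session))
#> <ibi_quality> longest valid segment 8760.3 s; 14 gap(s) [mean 38.2 s, sd 12.0 s]
```

The simulated beat record drops out fourteen times (the generator logs the
schedule as ground truth); almost two and a half hours are continuously
valid.

```r
fused$stress <- ifelse(!fused$allocated | is.na(fused$priority), NA,
                       ifelse(fused$priority == 1L, "high", "low"))
fused$time <- fused$elapsed_time / 3600
phase_contrast(fused, "avg_eda_level", "stress", ref = "low",
               covariates = "time")
#> Per-class outcome:
#>  class   n   mean     sd
#>    low 625 2.7262 0.4134
#>   high 179 2.6712 0.1470
#> Model-based contrast (lm):
#>      estimate       se  df        t p
#> high 0.064622 0.006271 801 10.30537 0
```

Adjusted for time-of-shift (the tonic level drifts upward all shift, so
call phase is confounded with time), high-stress windows run 0.065
microsiemens above low-stress windows — the elevated skin-conductance-
response rate the generator injected — at p ≪ 0.001. The raw class means
alone would mislead here: they mix the injected effect with where in the
shift the calls happened to fall.

For multi-officer studies, stack fused tables with `stack_shifts()` and
fit the full trajectory model:

```r
fit <- fit_mmta(avg_eda_level ~ time * intervention, data,
                random = ~ 1 + time)
summary(fit)
```

A command-line wrapper over the same functions is installed at
`inst/scripts/shiftsense.R` (`simulate`, `extract`, `fuse`, `fit`
subcommands).

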