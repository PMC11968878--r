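# steerscope

Kinematic and neural analysis of steering versus exploratory turns in
larval zebrafish.

Swimming zebrafish larvae change heading with two distinct maneuvers:
rapid **steering turns** — large asymmetric tail bends (peak tail angle
typically > 40°) producing sharp heading changes — and slow **exploratory
turns** — shallow bends (< 20°) during routine swimming. steerscope is an
R package for the analysis that separates the two and links turn amplitude
to neural recruitment:

* **Bout segmentation** — tail-angle peaks anchor fixed 40-frame bout
  windows (`[f1 − 9, f1 + 30]`, 0-based frames); per bout: mean bout angle,
  maximum tail amplitude, head change, tail-peak-to-head delay.
* **Turn classification** — unsupervised time-series k-means on the tail
  segments with dynamic time warping (DTW) as the distance, followed by a
  supervised cubic KNN (Minkowski `p = 3`, `k = 10`) on the two kinematic
  features:

  steering vs exploratory by `argmin_c DTW(x, centroid_c)`, then
  `label(q) = majority{ label(x(1)), …, x(k) nearest under (Σ|Δz|³)^{1/3} }`.
* **Calcium analysis** — `ΔF/F = (F′ − F0)/F0` with `F′ = F − Fb` and `F0`
  the mean over the quietest 5-s window; Gaussian + Savitzky–Golay
  smoothing; amplitude `Fa = Fmax − F0`; ROIs with `Fa > 0.3` (strict)
  count as responsive, response rate `n1/n`; ipsi/contra asymmetry.
* **Electrophysiology** — spike onsets at `dV/dt > 10 V/s` with the firing
  threshold read at the onset sample; per-bout recruitment curves with a
  bracketing threshold estimator; OLS of spike count on tail angle or beat
  frequency; PSP amplitude (baseline-to-peak), 10 %-rise onset and
  synaptic delay from sweep averages; gap-junction coupling coefficients
  `CC = ΔV_post / ΔV_pre`.
* **Synthetic data** — a seeded generator (kinematics, threshold-gated
  spiking, GCaMP-like fluorescence, paired recordings with ~0.8 ms
  synaptic delay) with documented ground truth, so the whole pipeline is
  testable end to end without any recordings. Head–tail coupling noise is
  calibrated via `σ = sqrt(a² Var(A)(1 − R²)/R²)` to hit target regression
  strengths (defaults R² = 0.3916 steering, 0.1163 exploratory).

It is aimed at behavioral/systems neuroscientists who have tail-tracking
output (e.g. from ZebraZoom-style trackers), ROI fluorescence traces, or
intracellular recordings, and want a tested, scriptable version of this
analysis chain.

## Worked example

```r
library(steerscope)

trial <- generate_trial(kinematics_config(trial_duration = 120), seed = 7)
bouts <- segment_bouts(trial$trace)
res   <- classify_pipeline(bouts, seed = 1)
res$class_summary[, c("label", "n", "median_amp", "mean_head_change")]
#>        label  n median_amp mean_head_change
#>  exploratory 59   10.70820         7.320586
#>     steering 64   56.70973        35.571500

st  <- res$features[res$features$label == "steering", ]
reg <- linear_regression(st$max_tail_amplitude,
                         ifelse(st$side == "right", 1, -1) * st$head_change)
sprintf("steering head~tail: slope %.3f, R2 %.3f, n %d",
        reg$slope, reg$r_squared, reg$n)
#> "steering head~tail: slope 0.629, R2 0.420, n 64"

truth <- trial$bouts$class[match(res$features$f1, trial$bouts$f1)]
mean(res$features$label == truth)
#> 1

rec <- simulate_paired_recording(paired_config(), seed = 7)
sprintf("synaptic delay: %.3f ms (mean of %d sweeps)",
        mean(psp_delays(rec)), rec$cfg$sweeps)
#> "synaptic delay: 0.828 ms (mean of 50 sweeps)"
```

The 123 detected bouts split into 59 exploratory (median peak amplitude
10.7°) and 64 steering (56.7°) events, in full agreement with the
generator's ground truth; the steering-class head-on-tail regression
recovers the generative slope (0.6°/°) and a coupling strength near the
calibrated target; and the PSP-onset estimator reads the ~0.8 ms
monosynaptic delay off 50 simulated sweeps.

A thin CLI wraps the same functions
(`inst/cli/steerscope simulate|segment|classify|calcium|ephys|report`);
see the script header for usage, and `vignettes/steerscope-methods.Rmd`
for the full model description, parameter defaults and design choices.

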