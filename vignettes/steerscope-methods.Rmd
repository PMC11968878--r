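---
title: "Methods: turn classification and neural-recruitment analysis in steerscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turn classification and neural-recruitment analysis in steerscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerscope)
```

# The problem

Larval zebrafish adjust their heading with two kinematically distinct turn
types: rapid **steering turns**, large asymmetric tail bends (peak tail
angles typically above 40°) that produce sharp heading changes, and slow
**exploratory turns**, shallow bends (below 20°) during routine swimming.
steerscope implements the computational side of an analysis that (i)
segments tail-angle recordings into discrete locomotor bouts, (ii)
classifies each bout as steering or exploratory, and (iii) relates turn
amplitude to neural recruitment measured by calcium imaging and
intracellular recording. Because the raw recordings behind such analyses
are not generally available, the package ships a seeded synthetic-data
generator with documented ground truth; every downstream stage is exercised
and tested against that truth.

# Bout segmentation

A trial is a pair of per-frame angle series (tail, head; degrees; 250
frames/s by default; positive tail angle = rightward bend). Bouts are
detected as local maxima of the rectified tail angle with a minimum height
(default 5°, below the smallest exploratory amplitudes we simulate) and a
minimum peak separation (default 40 frames, the bout-window length). When
two candidate maxima are closer than the minimum separation, the higher one
wins; plateau ties resolve to the earlier frame. Rectification means left
and right turns are treated identically.

Each peak frame `f1` anchors a fixed 40-sample window: the ten frames up to
and including `f1` plus the thirty frames after it, i.e. the closed
interval `[f1 - 9, f1 + 30]` in 0-based frame coordinates. Peaks whose
window would leave the trace are **discarded, not padded**, so every
segment passed to the classifier has exactly 40 samples — a requirement for
batch time-series clustering. Per bout we compute:

* `mean_bout_angle` — the signed arithmetic mean of the tail segment. The
  underlying quantity is the integral of the tail oscillation over the
  bout; since all windows have the same length, the mean is that integral
  up to a constant factor. A rectified integral would be the alternative
  reading; the signed mean is used because it preserves turn direction, and
  the choice only rescales one classifier feature.
* `max_tail_amplitude` — maximum rectified tail angle in the window.
* `head_change` — head angle at the window end minus at the window start.
* `peak_to_head_delay` — frames from `f1` to the half-rise crossing of the
  head change. The half-rise landmark is a package choice; any fixed
  fraction would do, and the generator's head step makes the measured delay
  equal the generative lag exactly.

# Turn classification

Classification is two-stage, mirroring common practice of bootstrapping a
supervised classifier from unsupervised structure:

1. **Time-series k-means with DTW.** The 40-sample tail segments
   (rectified by default; a `signed` switch disables this) are clustered
   with `k = 2` using dynamic time warping. `dtw_distance()` is the
   classical dynamic program over monotone step set
   `{(1,0), (0,1), (1,1)}` with local cost `|x_i − y_j|`; ties prefer the
   diagonal step so paths are deterministic. Inside k-means the local cost
   is squared and centroids are updated by DTW-barycenter averaging (each
   centroid sample becomes the mean of member samples aligned onto it);
   with squared costs and mean updates the within-cluster inertia is
   provably non-increasing per iteration, which the test suite asserts
   over 100 seeded runs. The cluster with the larger median
   `max_tail_amplitude` is annotated *steering*. In the original workflow
   this annotation came from watching the videos; a `labels` argument
   allows that manual override.
2. **Cubic KNN.** A k-nearest-neighbour classifier (`k = 10`, Minkowski
   exponent `p = 3`, unweighted votes — the presets of the "cubic KNN"
   learner in common classification toolboxes) is trained on the two
   scalar features, standardized to zero mean and unit variance because
   the features live on different scales. Vote ties are broken by the
   single nearest neighbour. The reported labels are the KNN predictions,
   and the fitted model serializes to JSON for reuse on new bouts.

Whether the original clustering stage consumed full tail-angle curves or
scalar summaries is ambiguous; steerscope clusters the curves (the literal
reading of *time-series* k-means). Since the scalar features are
deterministic functions of the curves, both readings separate the default
amplitude classes, and the supervised stage operates on scalars either way.

Degenerate inputs are reported, not silently classified: fewer than 10
bouts or all-identical segments raise errors, and when the two clusters'
median amplitudes differ by less than 10° (no amplitude-separated
structure, e.g. an all-exploratory recording) the pipeline warns and
returns a single-label output with no KNN model.

# Calcium analysis

For each ROI with raw fluorescence `F` and background `Fb`:
`F' = F − Fb`; the baseline `F0` is the mean of `F'` over the contiguous
5-s window with the smallest rolling mean — an operational reading of "a
5-s period of inactivity" that needs no event information; and
`ΔF/F(t) = (F'(t) − F0)/F0`. ΔF/F is invariant to gain applied to `F'` and
to offsets added to both `F` and `Fb` (tested properties). The series is
smoothed by a Gaussian kernel (SD 2 frames, truncated at 3 SD, reflective
boundaries) followed by a Savitzky–Golay filter (window 7, order 3, via
`signal::sgolayfilt`); both parameter sets are configuration keys since no
canonical values exist. The peak of the smoothed series is `Fmax`, and the
calcium signal amplitude is `Fa = Fmax` minus the smoothed series' own
baseline over the same quiet window (≈ 0), making `Fa` a ΔF/F-scale
quantity. The responsiveness cutoff `Fa > 0.3` is implemented as a strict
inequality, and a configuration switch would let users apply it on another
scale if their calibration differs. Population summaries count responsive
ROIs (`n1` of `n`, rate `n1/n` exactly) and average the per-trial
max-normalized amplitudes by side; `side_asymmetry()` reports ipsilateral
minus contralateral differences in rate and normalized amplitude.

# Electrophysiology

* **Spike detection**: spike onsets are the first samples of excursions
  where dV/dt (central differences; with mV and kHz units, mV/ms = V/s)
  exceeds 10 V/s; the firing threshold is the membrane potential at that
  sample; the spike time is the following AP peak; onsets within a 2-ms
  refractory window merge.
* **Recruitment curve**: per-bout (peak tail amplitude, spike count)
  pairs. The minimal recruitment angle is the smallest amplitude among
  active bouts, and the recruitment threshold estimate is the midpoint
  between the largest silent amplitude below it and the smallest active
  amplitude — always bracketed by the two, and undefined (reported `NA`)
  when the neuron never fires or no silent bout lies below the first
  active one. The angle paired with each bout is the bout's *peak*
  amplitude (not the instantaneous angle at spike time), consistent with
  how recruitment-angle plots are axis-labelled.
* **Count regressions**: ordinary least squares (`stats::lm`) of spike
  count on amplitude (active bouts by default, as recruitment plots are
  drawn from firing events) or on tail-beat frequency, reporting slope,
  `R²` and the two-sided slope-test p-value.
* **PSP measurement**: sweeps aligned on the presynaptic AP marker are
  averaged (30–60 consecutive sweeps is the norm; per-sweep measurement is
  available); baseline is the pre-marker mean; the extremum after the
  marker sets sign and amplitude (absolute baseline-to-peak, so IPSP
  amplitudes are positive); onset is the first crossing — linearly
  interpolated between samples — of baseline plus 10 % of the amplitude in
  the PSP direction, and the synaptic delay is onset minus AP time. The
  10 % criterion is a package choice (the onset landmark is never defined
  where delays are reported) and is a configuration key. For the default
  PSP kinetics it biases the delay upward by well under one 20-kHz
  sampling interval; amplitudes below five baseline SDs flag the delay
  unreliable.
* **Coupling coefficient**: postsynaptic over presynaptic steady-state
  deflection, reported separately for depolarizing and hyperpolarizing
  pulses.

# The synthetic generator

`generate_trial()` emulates the study conditions with documented ground
truth:

| Parameter | Default | Why |
|---|---|---|
| frame rate | 250 fps | behavioral video standard for this preparation |
| bout rate | 1 bout/s | typical spontaneous/OMR bout frequency |
| steering amplitude | truncated normal, mean 55°, SD 15°, support [40°, 90°] | steering turns exceed 40° |
| exploratory amplitude | truncated normal, mean 12°, SD 4°, support [5°, 20°) | exploratory turns stay below 20° |
| tail-beat frequency | 20 Hz | larval swim beat range |
| head slope | 0.6°/° | linear head–tail coupling, both classes |
| head noise SD | calibrated | see below |
| recruitment threshold θ | 40° (steering neurons) | activation only above ~40° |
| spike gain g | 0.2 spikes/° | 40–90° bouts yield ~1–10 spikes |
| synaptic delay | 0.8 ms mean, 0.05 ms jitter | monosynaptic latency |
| calcium kernel | rise 0.1 s, decay 1.8 s | GCaMP6s-like kinetics |

Choices worth explaining:

* **Bout waveform.** No generative waveform is specified anywhere, so each
  bout is a half-sine rise to the drawn peak followed by a damped cosine at
  the beat frequency (decay constant 8 frames), signed toward the bout's
  side and confined to the 40-frame window. The peak sample equals the
  drawn amplitude exactly, giving sharp truth for peak detection, and the
  oscillatory decay gives DTW realistic within-bout structure.
* **Head step.** The head angle steps by `0.6 × amplitude + ε` three
  frames after the tail peak (tail leads head; the generative lag is a
  modeling choice since only the existence of a delay is established).
* **Noise calibration.** `calibrate_head_noise()` returns
  `σ = sqrt(a² Var(A) (1 − R²)/R²)`, the unique noise SD for which the
  population R² of head change on amplitude equals the target. The default
  targets are R² = 0.3916 (steering) and 0.1163 (exploratory), the
  reported head–tail regression strengths, with Var(A) the closed-form
  truncated-normal variance. Because the head step is directed toward the
  turn side, the calibrated regression uses the *ipsiversive* head change
  (side × head_change) as the response.
* **Arrivals.** Poisson bout times are thinned to a minimum peak
  separation of 41 frames, so windows never overlap and segmentation
  completeness is testable exactly.
* **RNG protocol.** One root seed; stream order is bout count → bout
  times → sides → classes → amplitude quantiles (inverse-CDF truncated
  normal) → head noise. Tests re-draw the stream independently to verify
  the protocol.
* **Spiking rule.** An ipsilateral steering neuron fires
  `ceiling(g (A − θ))` spikes when the bout amplitude `A` exceeds θ and is
  otherwise silent; exploratory-class neurons fire `round(g A)` on
  ipsilateral exploratory bouts. The ceiling form makes *firing begin at
  the threshold* — a neuron active only above ~40° is active just above
  40°, not 2.5° later — which is what the recruitment-threshold estimator
  measures; with `g = 0` neurons stay silent. Spikes are placed
  deterministically within the 30 frames after the peak.
* **Calcium / paired recordings.** Fluorescence is a unit-peak
  double-exponential kernel per spike, scaled and superposed linearly over
  a constant `Fb + F0_cell`, plus optional Gaussian noise. Paired sweeps
  hold one AP marker and a PSP (`(1 − e^{−t/τr}) e^{−t/τd}`, unit peak;
  rise 0.2 ms, decay 5 ms — fast kinetics appropriate for strong
  monosynaptic inputs onto large motoneurons) whose onset follows the
  marker by an independent Gaussian delay draw; IPSPs deflect negative.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: tracking noise and midline-estimation error in
the angle traces; inter-bout postural drift; amplitude overlap between
turn classes (real steering and exploratory amplitudes may not be cleanly
separated, so real-data classifier accuracy will be lower than the ≥ 95 %
seen here); bursty or history-dependent bout timing; calcium indicator
nonlinearity and saturation; movement artifacts in fluorescence; and
active membrane conductances shaping PSPs. Parameter-recovery results on
this generator demonstrate estimator correctness, not field performance.

# Numerical choices and problem sizes

Angles are degrees, times seconds (ms in electrophysiology), frames
0-based in all tables and CSVs. Peak-detection ties go to the earlier
frame; DTW ties to the diagonal step; KNN vote ties to the nearest
neighbour. The test suite and the acceptance script run entirely on
generated data at sizes chosen to make their statistical assertions sharp:
200 bouts spanning 10–80° for threshold recovery (±2°), 50 paired sweeps
for delay recovery, 10⁴ bouts per class for the amplitude-support checks,
1761 steering / 2603 exploratory bouts (the reported event counts) for the
calibrated regressions, 700 mixed bouts for end-to-end classification, and
exhaustive DTW validation against a path-enumeration oracle on all ternary
series of length ≤ 4.

# Limitations

The classifier assumes two classes; a third gait would require changing
`k` and the annotation rule. The recruitment-threshold estimator needs
silent bouts below the firing range — a neuron firing on every observed
bout yields only an upper bound (`min_recruitment_angle`). The ΔF/F
baseline search assumes the trace contains at least one quiet 5-s stretch.
The PSP onset criterion is amplitude-relative, so very slow-rising PSPs
acquire a larger delay bias. None of the statistical hypothesis tests
reported alongside such analyses (t-tests, ANOVA and the like) are
reimplemented here; base R provides them.
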