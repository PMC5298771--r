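---
title: "Threshold-based fall detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based fall detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallwatch)
```

## The detection problem

A waist-worn triaxial accelerometer samples body acceleration at 200 Hz
(axis convention: +z forward, +y along gravity, +x to the wearer's
right). Trials are short recordings of either an activity of daily
living (ADL: walking, jogging, sitting down, lying down, jumping) or a
fall. The detector must flag falls while ignoring ADLs, including
deliberately confusable ones: jumps share the free-fall signature of a
fall, and lying down ends in the same posture a completed fall does.

`fallwatch` implements the classical threshold pipeline for this
problem:

1. **Preprocessing** — a causal 4th-order Butterworth low-pass at 5 Hz
   per axis, switchable off to study its effect.
2. **Feature extraction** — fourteen time-domain features (C1 to C14)
   over full-overlap sliding windows.
3. **Classification** — a trial is called a fall iff the trial-level
   maximum of one feature series strictly exceeds a threshold.
4. **Validation** — class-stratified 10-fold cross-validation with
   sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP) and the
   balanced accuracy AC = (SE+SP)/2, which tolerates unbalanced class
   counts.

Two threshold policies are fitted on training scores: **T1** maximizes
training AC (scanned over all midpoints between consecutive distinct
scores, which is exhaustive because the decision rule is piecewise
constant; AC ties break toward higher SE, then the lower threshold),
and **T2** sits just below the minimum training fall score
(`min(fall) - 1e-6 * max(spread, 1)`), so training sensitivity is 1 by
construction and specificity pays the price.

## The fourteen features

With $\vec a[k] = (a_x, a_y, a_z)$ in g and a window of $N_v$ samples
ending at $k$ (stride 1, "full overlap"):

| Code | Definition | Window |
|------|-----------|--------|
| C1 | $\sqrt{a_x^2+a_y^2+a_z^2}$ (sum vector magnitude) | per sample |
| C2 | $\sqrt{a_x^2+a_z^2}$ (horizontal plane) | per sample |
| C3 | norm of per-axis ranges $\max-\min$ over the window | 1 s |
| C4 | $\operatorname{atan2}(\sqrt{a_x^2+a_z^2},\,-a_y)$ | per sample |
| C5 | population sd over the window of $\operatorname{atan2}(\sqrt{a_x^2+a_z^2},\,a_y)$ | 1 s |
| C6 | dot product of mean $(a_x,a_z)$ over the previous and current adjacent windows | 1 s |
| C7 | $\lVert\vec a(k)-\vec a(k-N_v+1)\rVert / \Delta t$ (jerk) | 1 s |
| C8 | $\sqrt{\sigma_x^2+\sigma_z^2}$, per-axis population sd over the window | 1 s |
| C9 | $\sqrt{\sigma_x^2+\sigma_y^2+\sigma_z^2}$ | 1 s |
| C10 | $\frac1N(\int\lvert a_x\rvert+\int\lvert a_y\rvert+\int\lvert a_z\rvert)\,dt$ (SMA) | 0.5 s |
| C11 | horizontal-plane SMA | 0.5 s |
| C12 | $\int\sqrt{a_x^2+a_y^2+a_z^2}\,dn$ over the sample index | 1 s |
| C13 | $\int\sqrt{a_x^2+a_z^2}\,dn$ | 1 s |
| C14 | $\frac1N\sqrt{(\int a_x\,dt)^2+(\int a_z\,dt)^2}$ (velocity approx.) | 0.5 s |

All integrals use the trapezoid rule with limits $k-N_v+1$ to $k$.
Windowed values are emitted only once a complete window exists (no
padding, no partial windows), so a windowed series has
`length(trace) - nv + 1` values and C6 (which needs two adjacent
windows) starts at `2 * nv`.

Several published formulations of these features are typographically
ambiguous; where a reading had to be chosen it is documented on the
function and, where reasonable, the alternative reading is available
behind a flag:

* **C3** — per-axis peak-to-peak ranges combined in quadrature
  (default), or the range of the magnitude signal
  (`c3_mode = "magnitude"`).
* **C5** — interpreted as the dispersion of the instantaneous trunk
  tilt within the window.
* **C6** — previous vs current *non-overlapping* windows,
  $[k-2N+1,k-N]$ and $[k-N+1,k]$.
* **C7** — full 3-axis difference vector (default) or horizontal-only
  (`mode = "horizontal"`).
* **C14** — the $1/N$ normalization is kept as printed;
  `normalize = FALSE` gives the physical velocity reading.
* Standard deviations use the population form (divide by $N$): windows
  are fixed-length signal statistics, not samples from which a
  population variance is being estimated.
* C10/C11/C14 normalize by $N = N_v$; C12/C13 integrate over the
  sample index ($dn = 1$, units g·samples) as printed, while C10/C11/C14
  integrate over time ($dt = 1/f_s$, units g·s).

Window defaults (0.5 s for C10/C11/C14, 1 s for the other dynamic
features) follow the validation-accuracy heuristics reported for this
device class; `window_grid_search()` reproduces that kind of
exploration on any grid.

## Numerical choices

The rolling statistics are O(n) regardless of window length: sums and
(population) variances via cumulative sums — each axis is centred by
its global mean first, which is mathematically neutral for a variance
but avoids catastrophic cancellation — and sliding extrema via the van
Herk/Gil–Werman block algorithm. Every feature is verified against a
naive window-by-window oracle at 1e-9 relative tolerance.

Filtering is causal (single forward pass, zero initial state), the way
an embedded real-time detector would run; group delay and a start-up
transient are accepted. The design is delegated to `signal::butter`
and the contract is tested on the frequency response itself: unit DC
gain, $1/\sqrt2$ at 5 Hz, at least 60 dB down at 50 Hz, monotone
magnitude. Filtering only begins to make sense for traces longer than
three filter orders; shorter traces are rejected.

T1's finite sentinels and T2's epsilon are relative to the score
spread with a floor of 1, so degenerate inputs (all scores identical)
still yield finite thresholds and the documented tie behaviour
(everything above the threshold is a fall; ties are ADL).

## The synthetic-trial generator

The package is verified end to end without human-subject recordings.
`generate_dataset()` draws labelled trials whose *statistical
structure* matches what the analysis assumes; waveforms are parametric
closed forms (sinusoids, raised cosines, decaying oscillations), not
biomechanics.

* **Postures** are unit gravity vectors plus white noise: standing
  (0, 1, 0) g, lying supine (0, 0, 1), prone (0, 0, −1), lateral
  (±1, 0, 0).
* **Gait** (walk 1.4–2.0 Hz, jog 2.2–3.0 Hz) is a vertical fundamental
  of 0.15–0.35 g (walk) or 0.5–0.9 g (jog) with a 0.3-amplitude second
  harmonic and 0.5/0.25 horizontal fractions. Long gait trials last
  100 s, as in the recording protocol this emulates.
* **Sit** trials are smooth raised-cosine transients of 0.4–1.2 g with
  the standing gravity direction preserved.
* **Lie** trials roll the gravity vector onto a lateral lying
  orientation over 2.5 s, hold it, and roll back, with a gentle
  transient. This family matters: a completed fall ends lying, so
  without lying ADLs the constant 1 g horizontal gravity of the
  post-fall phase would let any horizontal-amplitude feature separate
  the classes by *posture* alone — a shortcut the real protocol's
  lying activities deliberately remove.
* **Jump** trials contain a 0.15–0.30 s near-weightless flight then a
  vertical landing spike of 1.0–2.5 g with a 0.2 forward leak —
  the classic false-positive generator.
* **Falls** are a pre-fall activity (walk, jog, stand or sit), then a
  critical phase of 0.3–0.5 s: a free-fall dip down to 0.05–0.35 g in
  its first half and an impact deceleration of 1.5–6.0 g along the
  fall direction in its second half (150–250 ms: trunk impacts at the
  waist are comparatively slow events, well inside the 5 Hz filter
  band; the lower amplitude bound covers hand-dampened falls). The
  gravity vector then settles onto the lying orientation over 1.2 s
  while the body rings down at 4 Hz (amplitude half the impact, time
  constant 0.6 s) with a small one-sided settling bias along the
  ground normal (ground contact only pushes, so the aftermath is not
  mean-neutral in magnitude). The impact peak sample is annotated as
  ground truth.

**Cohorts.** A single multiplier `cohort_scale` (young 1.0, elderly
0.7 by default) scales every *dynamic* component; gravity and the
gravity reorientation of a fall are physics and do not scale. The
elderly cohort also never draws the jump family, mirroring the
protocol's medical exclusions. The 0.7 default is a free choice — the
emulated study reports the amplitude shift only qualitatively — and is
exposed in the configuration.

**Reproducibility.** One root seed; each trial is generated under a
deterministically derived child seed, so datasets are byte-identical
for a given (config, seed) and independent of generation order.

**Quantization.** Traces are passed through the 13-bit/±16 g ADC model
(round, clip, read back), so synthetic files contain plausible integer
counts and downstream code sees quantized data by default.

### What the generator does and does not show

The generator reproduces the *directions* the analysis is about:
falls score above ADLs in amplitude features; a threshold trained on
the young cohort loses sensitivity on the amplitude-shrunk elderly
cohort while elderly-trained thresholds come out lower; T2 buys
sensitivity at a specificity cost that grows when fall impacts overlap
jump landings. Classes are constructed to overlap moderately in every
amplitude feature — a threshold analysis of cohort shift is only
informative in the overlap regime. Passing tests on synthetic data
therefore demonstrates the pipeline's correctness and these
qualitative trade-offs; they do not certify performance numbers on
real recordings, which depend on biomechanical variability (inter-step
irregularity, postural sway, device placement, real impact dynamics)
that the closed-form waveforms do not model. Gyroscope channels are
emitted as zeros and never featurized.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
desk scale: 200 ADL + 100 fall trials per cohort at the protocol's
native durations (100 s gait trials, 15 s falls) and 200 Hz, with
10-fold cross-validation; feature-oracle equivalence uses 100 random
2 s traces. These sizes give stable fold statistics while keeping a
complete run in tens of seconds.

## Known limitations

* Trial-level classification only: no online alarm latency, no
  persistence rule (a single sample above threshold suffices), no
  false-alarm-button simulation beyond the T2 specificity report.
* Folds stratify by class at the trial level; subject-level grouping
  (for leakage-sensitive uses) is available by passing precomputed
  fold ids to `cross_validate()`.
* The spec of this problem family sometimes treats the trunk-tilt
  dispersion C5 as translation-invariant; it is not (the tilt angle is
  a nonlinear function of the acceleration vector), and the package
  tests shift-invariance only for the range/difference/deviation
  features C3, C7, C8, C9.
* No resampling studies: the minimum-rate question (how far below
  200 Hz a detector could sample) is out of scope.
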