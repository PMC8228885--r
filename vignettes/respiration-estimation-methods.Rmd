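---
title: "Estimating respiratory motion from two inertial sensor nodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiratory motion from two inertial sensor nodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respgate)
```

## The problem

Respiratory motion blurs emission tomography images: over a multi-minute
acquisition the heart and abdominal organs move by 0.5–2 cm with each breath.
Amplitude gating mitigates this by splitting the acquisition into bins by the
instantaneous value of a respiration signal, so each bin is nearly
motion-free. Clinically the respiration signal comes from an optical
marker-block tracker; `respgate` implements an alternative that needs only
two adhesive IMU nodes — one on the sternum, one on the abdomen — and
estimates both the *waveform* and the *physical amplitude in centimetres* of
the breathing motion.

## The estimation model

All streams are linearly resampled to a common grid at `fs = 100` Hz. Two
complementary signals are then extracted.

**Shape signal `s(t)`.** Breathing tilts the sternum node, and the
projection of gravity onto the node's x/y accelerometer axes traces the
breathing waveform. Both channels are smoothed by a causal moving average of
`floor(0.8 fs)` samples, a PCA basis is fitted once from the first 60 s
(`floor(60 fs)` samples), and `s(t)` is the projection of the mean-centred
channels onto the first principal direction. `s(t)` has an excellent
waveform but arbitrary sign and arbitrary units. The causal window delays
`s(t)` by `(w - 1)/2` samples — about 0.4 s in the respiration band, a
figure the tests verify by cross-correlation.

**Position signal `p(t)`.** The abdomen node's six axes feed a
gradient-descent orientation filter (gyroscope integration corrected toward
gravity alignment with gain `beta`, the 6-axis variant without a
magnetometer). Rotating the measured specific force into the world frame
and subtracting `g = 9.81` m/s² leaves the vertical respiratory
acceleration, which is twice integrated (time-weighted cumulative sum); each
integration is followed by a zero-phase second-order Butterworth high-pass
at `f_B = 0.2` Hz that removes the unknown integration constants and
low-frequency drift. `p(t)` carries the physical polarity and a centimetre
scale, but a less faithful waveform.

**Fusion.** The two signals are synchronised by scanning all grid delays in
`[-2, 2]` s for the maximum *magnitude* of their mid-half correlation; the
correlation's sign at that lag gives the polarity `q ∈ {+1, −1}`. A signed
maximum would be unable to return a negative polarity at all — for an
inverted shape signal it locks onto a half-period-shifted positive side
lobe — so the magnitude criterion is the only self-consistent reading, and
the randomized-sign property test below exercises exactly this. The fused
signal is

    r_wobc(t) = q * sqrt(p_var(t) / s_var(t)) * (s(t) - s_avg(t)),

with `s_avg` a 10 s trailing mean and both variances 60 s trailing
(population) variances maintained by Welford-style add/remove updates. The
square root makes the factor a ratio of standard deviations, which is what
maps the shape signal's arbitrary units onto centimetres. Because `p` is
high-passed it carries no baseline; slow drift is recovered from the shape
signal instead,

    b(t) = (mavg(s, 60 s) - mean(s)) * sd(r_wobc) / sd(s),
    r(t) = r_wobc(t) + q * b(t).

The standard-deviation ratio is written here as `sd(r)/sd(s)`: the inverse
ratio would map the baseline to the shape signal's units, making the
correction numerically inert, so this orientation is the only one that can
have the intended effect. Global (not windowed) statistics are used, which
avoids a circular dependence of `r` on `b`.

**Calibration.** `gamma = mean(reference cycle magnitudes) / mean(estimated
cycle magnitudes)` rescales `r` so the two mean cycle magnitudes agree
exactly. Quantile-based gating is invariant to this positive rescaling (a
property the test suite asserts); calibration matters when the estimate must
stand in for the reference signal in physical units.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `fs` | 100 | Hz | common analysis grid |
| `w_avg_s` | `floor(0.8 fs)` | samples | shape-channel smoothing; sets the ~0.4 s delay |
| `n_circ` | `floor(60 fs)` | samples | PCA fitting buffer (first 60 s) |
| `g` | 9.81 | m/s² | gravity removed from world-z acceleration |
| `f_b` | 0.2 | Hz | high-pass cutoff of both integration stages |
| `w_avg_f1` | `floor(10 fs)` | samples | window of `s_avg` |
| `w_avg_f2` | `floor(60 fs)` | samples | window of both variances |
| `w_avg_f3` | `floor(60 fs)` | samples | window of the baseline estimate |
| `d_max` | 2 | s | delay search half-range |
| `madgwick_beta` | 0.1 | – | orientation-filter correction gain |

`madgwick_beta` is a declared default, not a literature constant: larger
values track accelerometer gravity faster but let breathing accelerations
perturb the orientation; 0.1 is a conventional trade-off for slow,
low-dynamics motion and is exposed in `algorithm_params()`.

## What the synthetic generator emulates — and what it does not

No public recording with this sensor layout exists, so the package ships a
generator used by every end-to-end test. A recording is a trough-to-trough
concatenation of asymmetric raised-cosine cycles (inspiration fraction 0.4),
chosen for C¹ continuity so that second derivatives — what accelerometers
measure — are well defined. Per-cycle periods and peak-to-trough amplitudes
are log-normal (defaults: 4 s, cv 0.1; 1 cm, cv 0.15, spanning the 0.5–1.7 cm
range typical of supine abdominal breathing), occasional deep breaths
(0.5/min, ×2 amplitude) are flagged invalid the way a reference system
rejects irregular cycles, and a slow sinusoidal baseline (0.3 cm, 300 s)
emulates posture drift. Nodes tilt linearly with displacement
(0.05 rad/cm sternum, 0.02 rad/cm abdomen — a modelling choice, as no
quantitative tilt–displacement relation is established); gravity and the
world-z linear acceleration are projected through that tilt, the sternum
node carries a fixed 0.4 rad mounting yaw so its two PCA channels are both
informative, and white noise is added (accel 0.003 m/s², gyro 0.002 rad/s,
order-of-magnitude datasheet values). The 25 Hz reference rides on the same
displacement with configurable gain and 0.02 cm noise.

The generator does *not* emulate cardiac (seismocardiographic) motion, bed
motion, sensor detachment, coughing, or non-stationary breathing-pattern
changes. Passing tests therefore show that the algorithm chain is correct
and accurate under plausible breathing statistics — not that it is robust to
every artifact of a clinical recording.

## Numerical choices

* **Resampling** is linear interpolation restricted to the common support of
  all streams (grid origin rounded up to a multiple of `1/fs`); respiration
  is far below Nyquist, so no anti-alias filter is applied.
* **Zero-phase filtering** pads with odd reflection of length 3× the filter
  order and starts each pass from step-response steady-state initial
  conditions, so the forward–backward result is reproducible bit-for-bit and
  edge transients stay bounded. A zero-phase pass applies the Butterworth
  magnitude twice; tests compare amplitudes against the closed form
  *including* this known gain.
* **Integration** starts at zero velocity/position with constant `1/fs`
  steps.
* **Degenerate data**: a zero-variance PCA buffer, zero shape-signal
  variance, equal gating thresholds and zero estimated cycle magnitude all
  raise classed errors rather than produce NaN; a locally vanishing shape
  variance holds the fusion scale at its last valid value.
* **Ties**: the delay search prefers the smallest |d|, negative first; gate
  bins are half-open with the top bin closed; a zero mid-half correlation
  defaults to polarity +1.
* **Peak detection** windows are half-open trigger-to-trigger intervals; a
  window without a local maximum falls back to its argmax.
* **Amplitude comparison**: the estimate's zero level is arbitrary (it
  descends from a mean-centred PCA projection), so the pointwise mean
  absolute error is computed by default after removing each signal's
  trailing 60 s moving average; `align = "none"` gives the literal pointwise
  definition. Cycle durations and magnitudes are offset-invariant either
  way.
* **VOI statistics** use the sample (n−1) standard deviation.

## Problem sizes used in validation

End-to-end accuracy is assessed on a 15-minute default subject (the full
pipeline runs in a few seconds); the delay-recovery property scans all 401
integer-sample delays in ±2 s on a 90 s record; polarity recovery uses 200
random seeds at 70 s each with the PCA sign randomized; moment checks of the
generator use ≥ 500 cycles. On the default subject the calibrated estimate
agrees with the simulated reference to ≤ 0.24 cm mean absolute amplitude and
≤ 0.44 min⁻¹ breathing-rate error — the levels the acceptance tests assert.

## Known limitations

* The shape filter's ~0.4 s causal delay is inherited by the fused signal;
  it cancels in cycle durations but contributes most of the residual
  pointwise amplitude error.
* The polarity and delay are estimated once per record; a polarity change
  mid-recording (e.g. node repositioning) is out of model.
* Two stages of zero-phase high-pass filtering attenuate slow breathing
  (≈ 30% amplitude at 0.25 Hz): absolute amplitudes require the
  gamma-calibration, while gating is unaffected by construction.
* Cycle rejection follows the reference system's validity flags; no
  self-contained cycle-quality classifier is provided.
* The orientation filter assumes a supine, quasi-static subject; gross body
  motion violates the gravity-alignment assumption.
```{r}
sessionInfo()
```
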