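# respgate

Respiratory motion estimation from two body-worn inertial measurement units
(IMUs), with amplitude-based gating for emission tomography and
gated-image quality metrics.

## The problem

Respiratory motion blurs PET images acquired over several minutes.
*Amplitude gating* divides the acquisition into bins by the instantaneous
value of a respiration signal so each bin is nearly motion-free. The
clinical respiration signal usually comes from an optical marker tracker,
which is time-consuming to set up and can lose line of sight. `respgate`
estimates the respiration signal instead from two adhesive MEMS sensor
nodes — one on the sternum, one on the abdomen — recovering both the
breathing waveform and its physical amplitude in centimetres, for
researchers working on motion-compensated PET and on wearable respiration
monitoring generally.

## The method

Both nodes are resampled to a common 100 Hz grid, then two signals are fused:

* **Shape signal** `s(t)` — first principal component of the moving-averaged
  (window `⌊0.8 fs⌋`) sternum accelerometer x/y channels; PCA basis fitted
  once from the first 60 s. Faithful waveform, arbitrary sign and units.
* **Position signal** `p(t)` — abdomen-node orientation from a
  gradient-descent (Madgwick-type) 6-axis filter; the world-z specific force
  minus `g` is twice integrated, each stage followed by a zero-phase
  2nd-order Butterworth high-pass at 0.2 Hz. Physical polarity and cm scale.

The signals are synchronised by the lag `d` maximising `|Σ s(t) p(t + d)|`
over the record's mid-half (`|d| ≤ 2` s); the correlation's sign at `d`
gives the polarity `q`. The fused signal is

```
r_wobc(t) = q · sqrt(p_var(t) / s_var(t)) · (s(t) − s_avg(t))
r(t)      = r_wobc(t) + q · b(t),   b(t) = (mavg(s, 60 s) − mean(s)) · sd(r_wobc)/sd(s)
```

with trailing moving statistics (10 s mean, 60 s variances) maintained by
sliding Welford updates. A subject constant
`γ = reference magnitude / estimated magnitude` calibrates absolute
amplitude; quantile gating is invariant to it. Per-cycle agreement with a
reference is summarised by the mean absolute breathing-rate error
`MAE_fB = (1/T_min) Σ_i |d_i − d_i^ref| / d_i^ref` and the mean absolute
amplitude error `mean |r − r_ref|` on drift-corrected signals.

Because no public recording with this sensor layout exists, the package
includes a synthetic generator (asymmetric raised-cosine cycles with period
and amplitude jitter, deep breaths, baseline drift, tilt + gravity
projection sensor physics, and a noisy 25 Hz reference with end-expiration
triggers) that every end-to-end test runs against. See the vignette
`vignettes/respiration-estimation-methods.Rmd` for the full model and the
design decisions.

## Worked example

```r
library(respgate)

gt   <- generate_breathing(breathing_config(duration = 900, seed = 1))
sens <- sensor_config()
rec  <- resample_to_grid(simulate_node(gt, "sternum", sens),
                         simulate_node(gt, "abdomen", sens), 100)
ref  <- simulate_reference(gt, sens)

est <- estimate_respiration(rec)
est
#> respiration estimate: 90299 samples, d = -0.40 s, q = +1

cal <- calibrate_amplitude(est$r,
                           detect_cycles(ref, gt$triggers, "reference"),
                           detect_cycles(est$r, gt$triggers, "estimate"))
rep <- compare_respiration(cal$r_cal, ref, gt$triggers, q = est$diagnostics$q)
rep
#> respiration comparison over 224 cycles:
#>   mean cycle magnitude: estimate 1.17 cm, reference 1.17 cm
#>   MAE amplitude: 0.181 cm
#>   MAE breathing rate: 0.412 1/min

cfg <- gating_config()   # 0.2/0.8 quantiles, 5 equidistant gates
assign_gates(cal$r_cal$value, compute_thresholds(cal$r_cal$value, cfg), cfg,
             cycle_validity_mask(cal$r_cal$time, gt$triggers, gt$cycle_validity))
#> amplitude gating: thresholds [-0.399, 0.419], 90299 samples
#>   preserved per gate (%): 11.78 13.49 11.59 11.75 10.54
#>   lost data: 40.86%
```

The estimate lags the reference by the shape filter's ~0.4 s causal delay
(`d = −0.40 s`); after γ-calibration the mean cycle magnitudes agree
exactly; the calibrated signal tracks the reference to 0.18 cm mean absolute
amplitude and 0.41 min⁻¹ breathing-rate error; gating at the 0.2/0.8
quantiles rejects ≈40% of samples plus the deep-breath cycles flagged
invalid.

A thin command-line front end over the same functions ships in
`inst/scripts/respgate` (`simulate | estimate | compare | gate | imgqc`).

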