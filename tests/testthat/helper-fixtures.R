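# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A resampled_record built directly from closed-form abdomen-node physics:
# world-z displacement disp_fun(t) in cm (with analytic first/second
# derivatives), optional tilt about x (rad/cm), no noise unless given.
sinusoid_record <- function(duration = 120, fs = 100, amp_cm = 0.5,
                            freq = 0.25, tilt_gain = 0, g = 9.81,
                            noise_sd = 0) {
  tt <- seq(0, duration, by = 1 / fs)
  w <- 2 * pi * freq
  disp <- amp_cm * sin(w * tt)                   # cm
  acc <- -amp_cm * w^2 * sin(w * tt) * 0.01      # m/s^2
  vel <- amp_cm * w * cos(w * tt)                # cm/s
  theta <- tilt_gain * disp
  f_tot <- g + acc
  accel <- cbind(0, f_tot * sin(theta), f_tot * cos(theta))
  gyro <- cbind(tilt_gain * vel, 0, 0)
  if (noise_sd > 0) {
    accel <- accel + matrix(rnorm(length(accel), 0, noise_sd), ncol = 3)
  }
  structure(list(time = tt,
                 node1_accel_xy = cbind(sin(w * tt), 0.5 * sin(w * tt)),
                 node2_accel_xyz = accel,
                 node2_gyro_xyz = gyro,
                 fs = fs),
            class = "resampled_record")
}

# small default synthetic subject, shared by several files
default_subject <- function(duration = 120, seed = 7, ...) {
  gt <- generate_breathing(breathing_config(duration = duration, seed = seed, ...))
  sens <- sensor_config()
  list(gt = gt,
       rec = resample_to_grid(simulate_node(gt, "sternum", sens),
                              simulate_node(gt, "abdomen", sens), 100),
       ref = simulate_reference(gt, sens))
}

# magnitude response of a digital filter at frequency f (Hz) for rate fs
filter_gain <- function(b, a, f, fs) {
  z <- exp(-2i * pi * f / fs * seq(0, max(length(a), length(b)) - 1))
  abs(sum(b * z[seq_along(b)]) / sum(a * z[seq_along(a)]))
}

# amplitude gain of one integrate_highpass stage at frequency f:
# zero-phase filtering applies the Butterworth magnitude twice
stage_gain <- function(f, fs = 100, f_b = 0.2) {
  bw <- signal::butter(2, f_b / (fs / 2), type = "high")
  filter_gain(bw$b, bw$a, f, fs)^2
}

# steady-state cycle magnitude: mean peak-to-trough over interior cycles
steady_magnitude <- function(x, fs, freq, discard_s = 30) {
  n <- length(x)
  keep <- (discard_s * fs):(n - discard_s * fs)
  x <- x[keep]
  per <- round(fs / freq)
  k <- floor(length(x) / per)
  mags <- vapply(seq_len(k), function(i) {
    seg <- x[((i - 1) * per + 1):(i * per)]
    max(seg) - min(seg)
  }, numeric(1))
  mean(mags)
}
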