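test_that("noiseless periodic construction has exact cycle counts and magnitudes", {
  cfg <- breathing_config(mean_period = 4, period_jitter_cv = 0,
                          mean_amplitude = 1, amplitude_jitter_cv = 0,
                          drift_amplitude = 0, deep_breath_rate = 0,
                          duration = 120, seed = 1)
  gt <- generate_breathing(cfg)
  expect_equal(length(gt$triggers), 31L)
  expect_equal(length(gt$cycle_validity), 30L)
  expect_true(all(gt$cycle_validity))
  expect_equal(gt$duration, 120)
  # every cycle magnitude (max - min) is exactly the configured amplitude
  for (i in 1:30) {
    w <- gt$displacement[gt$time >= gt$triggers[i] & gt$time <= gt$triggers[i + 1]]
    expect_equal(max(w) - min(w), 1.0, tolerance = 1e-12)
  }
  # displacement is zero at every trigger (troughs)
  expect_equal(breathing_displacement(gt, gt$triggers), rep(0, 31),
               tolerance = 1e-12)
})

test_that("period jitter reproduces the configured coefficient of variation", {
  cfg <- breathing_config(duration = 2400, period_jitter_cv = 0.1,
                          deep_breath_rate = 0, drift_amplitude = 0, seed = 11)
  gt <- generate_breathing(cfg)
  d <- diff(gt$triggers)
  expect_gt(length(d), 500)
  cv_hat <- sd(d) / mean(d)
  se <- 0.1 / sqrt(2 * (length(d) - 1))  # SE of a sample cv, normal approx
  expect_lt(abs(cv_hat - 0.1), 3 * se + 0.01)
})

test_that("generator is bit-identical for identical seeds and differs across seeds", {
  cfg <- breathing_config(duration = 60, seed = 5)
  a <- generate_breathing(cfg)
  b <- generate_breathing(cfg)
  expect_identical(a, b)
  sens <- sensor_config()
  expect_identical(simulate_node(a, "abdomen", sens),
                   simulate_node(b, "abdomen", sens))
  expect_identical(simulate_reference(a, sens), simulate_reference(b, sens))
  c <- generate_breathing(breathing_config(duration = 60, seed = 6))
  expect_false(identical(a$displacement, c$displacement))
})

test_that("static world gives a static sensor: accel (0,0,g), gyro zero", {
  gt <- generate_breathing(breathing_config(mean_amplitude = 1e-12,
                                            drift_amplitude = 0,
                                            deep_breath_rate = 0,
                                            duration = 10, seed = 1))
  sens <- sensor_config(accel_noise_sd = 0, gyro_noise_sd = 0)
  rec <- simulate_node(gt, "abdomen", sens)
  expect_equal(max(abs(rec$accel[, 1])), 0, tolerance = 1e-10)
  expect_equal(max(abs(rec$accel[, 2])), 0, tolerance = 1e-10)
  expect_equal(rec$accel[, 3], rep(9.81, nrow(rec$accel)), tolerance = 1e-9)
  expect_equal(max(abs(rec$gyro)), 0, tolerance = 1e-10)
})

test_that("accelerometer z-channel carries the closed-form second derivative", {
  # pure linear motion (no tilt): az = g + d2z/dt2 in m/s^2
  gt <- generate_breathing(breathing_config(mean_period = 4, period_jitter_cv = 0,
                                            mean_amplitude = 1, amplitude_jitter_cv = 0,
                                            drift_amplitude = 0, deep_breath_rate = 0,
                                            duration = 20, seed = 1))
  sens <- sensor_config(accel_noise_sd = 0, gyro_noise_sd = 0,
                        tilt_gain_node2 = 0)
  rec <- simulate_node(gt, "abdomen", sens)
  expected <- 9.81 + 0.01 * breathing_displacement(gt, rec$accel_time, deriv = 2)
  expect_equal(rec$accel[, 3], expected, tolerance = 1e-10)
})

test_that("gyroscope x-channel is the closed-form tilt rate", {
  gt <- generate_breathing(breathing_config(mean_period = 4, period_jitter_cv = 0,
                                            mean_amplitude = 1, amplitude_jitter_cv = 0,
                                            drift_amplitude = 0, deep_breath_rate = 0,
                                            duration = 20, seed = 1))
  sens <- sensor_config(accel_noise_sd = 0, gyro_noise_sd = 0,
                        tilt_gain_node2 = 0.1)
  rec <- simulate_node(gt, "abdomen", sens)
  expected <- 0.1 * breathing_displacement(gt, rec$gyro_time, deriv = 1)
  expect_equal(rec$gyro[, 1], expected, tolerance = 1e-10)
  # peak rate matches A/2 * k * gain for the rise segment of the first cycle
  k_rise <- pi / (0.4 * 4)
  expect_equal(max(rec$gyro[, 1]), 0.1 * 0.5 * k_rise, tolerance = 1e-6)
})

test_that("reference is the gain-scaled truth plus noise of the stated sd", {
  gt <- generate_breathing(breathing_config(duration = 300, seed = 3))
  sens0 <- sensor_config(reference_noise_sd = 0, marker_gain = 0.7)
  ref0 <- simulate_reference(gt, sens0)
  expect_equal(ref0$value, 0.7 * breathing_displacement(gt, ref0$time),
               tolerance = 1e-12)
  sens1 <- sensor_config(reference_noise_sd = 0.02, marker_gain = 0.7)
  ref1 <- simulate_reference(gt, sens1)
  resid <- ref1$value - 0.7 * breathing_displacement(gt, ref1$time)
  n <- length(resid)
  expect_lt(abs(sd(resid) - 0.02), 3 * 0.02 / sqrt(2 * (n - 1)))
})

test_that("unknown node role and invalid configs are rejected", {
  gt <- generate_breathing(breathing_config(duration = 10, seed = 1))
  expect_error(simulate_node(gt, "thorax"), class = "respgate_config_error")
  expect_error(breathing_config(mean_period = -1), class = "respgate_config_error")
  expect_error(breathing_config(mean_amplitude = 0), class = "respgate_config_error")
  expect_error(breathing_config(duration = 0), class = "respgate_config_error")
  expect_error(sensor_config(accel_noise_sd = -1), class = "respgate_config_error")
})

test_that("noise-free abdomen z-accel power concentrates in the breathing band", {
  gt <- generate_breathing(breathing_config(duration = 600, seed = 9))
  sens <- sensor_config(accel_noise_sd = 0, gyro_noise_sd = 0)
  rec <- simulate_node(gt, "abdomen", sens)
  z <- rec$accel[, 3] - mean(rec$accel[, 3])
  n <- length(z)
  fs <- sens$accel_fs
  pw <- Mod(fft(z))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  band <- half & freqs >= 0.8 / 4 & freqs <= 5 / 4
  expect_gte(sum(pw[band]) / sum(pw[half]), 0.90)
})

test_that("reference value at each trigger sits at a local minimum (noise-free)", {
  gt <- generate_breathing(breathing_config(duration = 120, seed = 2))
  sens <- sensor_config(reference_noise_sd = 0)
  ref <- simulate_reference(gt, sens)
  trig <- attr(ref, "triggers")
  interior <- trig[trig > ref$time[2] & trig < ref$time[length(ref$time) - 1]]
  for (tr in interior) {
    i <- which.min(abs(ref$time - tr))
    lo <- max(1, i - 2); hi <- min(nrow(ref), i + 2)
    # within one sample of the trigger there is a sample no larger than both
    # neighbours of the window
    expect_lte(min(ref$value[max(1, i - 1):min(nrow(ref), i + 1)]),
               min(ref$value[lo], ref$value[hi]) + 1e-12)
  }
})
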