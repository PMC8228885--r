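test_that("delay estimation is exact for injected integer-sample delays", {
  sub <- default_subject(duration = 90, seed = 31)
  s <- compute_shape_signal(sub$rec, algorithm_params())$value
  expect_equal(estimate_delay(s, s, 100, 2), 0)
  # oracle: construct p as s delayed by 37 samples
  n <- length(s)
  p <- c(rep(s[1], 37), s[1:(n - 37)])  # p(t) = s(t - 0.37)
  expect_equal(estimate_delay(s, p, 100, 2), 0.37, tolerance = 1e-12)
  expect_error(estimate_delay(s[1:500], p[1:500], 100, 2),
               class = "respgate_data_error")
})

test_that("polarity follows the sign of the mid-half correlation", {
  sub <- default_subject(duration = 90, seed = 32)
  s <- compute_shape_signal(sub$rec, algorithm_params())$value
  expect_equal(estimate_polarity(s, s, 0, 100), 1)
  expect_equal(estimate_polarity(s, -s, 0, 100), -1)
  set.seed(1)
  p <- 0.5 * s + rnorm(length(s), 0, 0.1 * sd(s))
  expect_equal(estimate_polarity(s, p, 0, 100), 1)
  expect_equal(estimate_polarity(s, numeric(length(s)), 0, 100), 1)
})

test_that("sliding Welford statistics equal the two-pass oracle", {
  set.seed(8)
  x <- rnorm(2000, mean = 5, sd = 2) + sin(seq_len(2000) / 50)
  for (w in c(2, 10, 137, 1000)) {
    st <- moving_stats(x, w)
    for (i in c(1, 2, w - 1, w, w + 1, 555, 2000)) {
      if (i < 1 || i > 2000) next
      win <- x[max(1, i - w + 1):i]
      expect_equal(st$avg[i], mean(win), tolerance = 1e-9)
      expect_equal(st$var[i], mean((win - mean(win))^2), tolerance = 1e-9)
    }
  }
  # full-vector agreement at 1e-9 relative for a realistic window
  w <- 137
  st <- moving_stats(x, w)
  direct_var <- vapply(seq_along(x), function(i) {
    win <- x[max(1, i - w + 1):i]
    mean((win - mean(win))^2)
  }, numeric(1))
  expect_lt(max(abs(st$var - direct_var) / pmax(direct_var, 1e-12)), 1e-9)
  expect_lt(max(abs(moving_stats(rep(2.5, 500), 60)$var)), 1e-12)
  expect_error(moving_stats(x, 1), class = "respgate_config_error")
})

test_that("variance-ratio fusion rescales the shape signal to the position scale", {
  fs <- 100
  tt <- seq(0, 300, by = 1 / fs)
  w <- 2 * pi * 0.25
  s <- sin(w * tt)
  p <- 3 * sin(w * tt)
  prm <- algorithm_params()
  fw <- fuse_wobc(s, p, 1, prm)
  # p identical to s: scale factor 1, r = s - s_avg
  fw_id <- fuse_wobc(s, s, 1, prm)
  expect_equal(fw_id$r_wobc, s - fw_id$s_avg, tolerance = 1e-9)
  # steady-state cycle magnitude matches p's (peak-to-trough 6) within 5%
  m <- steady_magnitude(fw$r_wobc, fs, 0.25, discard_s = 70)
  expect_equal(m, 6, tolerance = 0.05 * 6)
  # sign-flipped s with q = -1 leaves the fusion unchanged
  fw_neg <- fuse_wobc(-s, p, -1, prm)
  expect_equal(fw_neg$r_wobc, fw$r_wobc, tolerance = 1e-9)
  expect_error(fuse_wobc(numeric(1000) + 1, p[1:1000], 1, prm),
               class = "respgate_degenerate_error")
})

test_that("fusion scale is equivariant in the position signal's amplitude", {
  sub <- default_subject(duration = 180, seed = 33)
  prm <- algorithm_params()
  s <- compute_shape_signal(sub$rec, prm)$value
  p <- compute_polmag_signal(sub$rec, prm)$value
  f1 <- fuse_wobc(s, p, 1, prm)
  f3 <- fuse_wobc(s, 3 * p, 1, prm)
  m1 <- steady_magnitude(f1$r_wobc, 100, 0.25, discard_s = 70)
  m3 <- steady_magnitude(f3$r_wobc, 100, 0.25, discard_s = 70)
  expect_equal(m3 / m1, 3, tolerance = 0.01)
})

test_that("baseline estimation tracks slow drift at the fused signal's scale", {
  fs <- 100
  tt <- seq(0, 600, by = 1 / fs)
  w <- 2 * pi * 0.25
  prm <- algorithm_params()
  # zero-mean oscillation with no low-frequency content: baseline ~ 0
  s0 <- sin(w * tt)
  b0 <- estimate_baseline(s0, s0, prm)
  expect_lt(max(abs(b0[(60 * fs):length(b0)])), 0.05 * sd(s0))
  # drifting shape signal: baseline follows the drift, rescaled by sd(r)/sd(s)
  drift <- 0.002 * tt
  s1 <- sin(w * tt) + drift
  r1 <- 2 * sin(w * tt)  # stands in for r_wobc
  b1 <- estimate_baseline(s1, r1, prm)
  oracle <- (moving_average(s1, prm$w_avg_f3) - mean(s1)) * sd(r1) / sd(s1)
  expect_equal(b1, oracle, tolerance = 1e-12)
  warm <- tt > 120 & tt < 540
  drift_ma <- moving_average(drift, prm$w_avg_f3)
  expect_lt(mean(abs(b1[warm] - (drift_ma[warm] - mean(s1)) * sd(r1) / sd(s1))),
            0.1 * sd(r1))
  expect_error(estimate_baseline(s1, numeric(length(s1)), prm),
               class = "respgate_degenerate_error")
})

test_that("baseline correction is additive and improves drift tracking end-to-end", {
  expect_equal(baseline_correct(c(1, 2, 3), c(0, 0, 0), 1), c(1, 2, 3))
  expect_equal(baseline_correct(c(1, 2, 3), rep(0.5, 3), 1), c(1.5, 2.5, 3.5))
  # full pipeline on strongly drifting data: correction lowers the error
  # against the drift-carrying ground truth
  gt <- generate_breathing(breathing_config(duration = 600, drift_amplitude = 0.8,
                                            drift_period = 240,
                                            deep_breath_rate = 0, seed = 34))
  sens <- sensor_config()
  rec <- resample_to_grid(simulate_node(gt, "sternum", sens),
                          simulate_node(gt, "abdomen", sens), 100)
  prm <- algorithm_params()
  est <- estimate_respiration(rec, prm)
  d <- est$diagnostics
  r_wo <- est$r$value - d$q * d$b   # undo the baseline term
  truth <- breathing_displacement(gt, est$r$time)
  center <- function(x) x - mean(x)
  i <- (120 * 100):length(truth)
  mae_with <- mean(abs(center(est$r$value[i]) - center(truth[i])))
  mae_without <- mean(abs(center(r_wo[i]) - center(truth[i])))
  expect_lt(mae_with, mae_without)
})

test_that("gamma calibration equates mean cycle magnitudes exactly", {
  tt <- seq(0, 40, by = 0.01)
  r <- respiration_signal(tt, sin(2 * pi * tt / 4), unit = "cm", kind = "fused")
  peaks <- seq(1, 37, by = 4)
  cyc_est <- cycle_table(peaks, diff(peaks), rep(1.0, length(peaks) - 1), "estimate")
  cyc_ref <- cycle_table(peaks, diff(peaks), rep(0.68, length(peaks) - 1), "reference")
  cal <- calibrate_amplitude(r, cyc_ref, cyc_est)
  expect_equal(cal$gamma, 0.68)
  expect_equal(cal$r_cal$value, 0.68 * r$value)
  # already equal magnitudes: gamma 1, signal unchanged
  cal1 <- calibrate_amplitude(r, cyc_est, cyc_est)
  expect_equal(cal1$gamma, 1)
  expect_equal(cal1$r_cal$value, r$value)
  expect_error(calibrate_amplitude(r, cyc_ref,
                                   cycle_table(peaks, diff(peaks),
                                               rep(0, length(peaks) - 1), "estimate")),
               class = "respgate_degenerate_error")
})

test_that("estimated respiration is deterministic and carries diagnostics", {
  sub <- default_subject(duration = 90, seed = 35)
  e1 <- estimate_respiration(sub$rec)
  e2 <- estimate_respiration(sub$rec)
  expect_identical(e1$r$value, e2$r$value)
  d <- e1$diagnostics
  expect_lte(abs(d$d), 2)
  expect_true(d$q %in% c(-1, 1))
  expect_true(all(d$p_var >= 0) && all(d$s_var >= 0))
})
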