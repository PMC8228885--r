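#' Breathing model configuration
#'
#' Parameters of the synthetic ground-truth breathing generator. A recording
#' is a concatenation of breathing cycles running trough-to-trough; each cycle
#' is an asymmetric raised cosine (rise during inspiration, fall during
#' expiration), which is continuously differentiable so sensor accelerations
#' are well defined. Per-cycle period and peak-to-trough amplitude are drawn
#' from log-normal distributions; occasional deep breaths multiply a cycle's
#' amplitude; a slow sinusoidal baseline drift emulates posture and
#' muscle-tone changes.
#'
#' @param mean_period mean cycle duration, s.
#' @param period_jitter_cv coefficient of variation of cycle durations.
#' @param mean_amplitude mean peak-to-trough displacement, cm.
#' @param amplitude_jitter_cv coefficient of variation of cycle amplitudes.
#' @param asymmetry fraction of the cycle spent in inspiration, in (0, 1).
#' @param drift_amplitude amplitude of the sinusoidal baseline drift, cm.
#' @param drift_period period of the baseline drift, s.
#' @param deep_breath_rate expected deep-breath events per minute.
#' @param deep_breath_scale amplitude multiplier applied to deep-breath cycles.
#' @param duration requested recording length, s; the final cycle is completed
#'   so the record always ends at a trough.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return an object of class `breathing_config`.
#' @export
breathing_config <- function(mean_period = 4,
                             period_jitter_cv = 0.1,
                             mean_amplitude = 1,
                             amplitude_jitter_cv = 0.15,
                             asymmetry = 0.4,
                             drift_amplitude = 0.3,
                             drift_period = 300,
                             deep_breath_rate = 0.5,
                             deep_breath_scale = 2,
                             duration = 900,
                             seed = 1L) {
  if (mean_period <= 0) stop_config("mean_period must be positive")
  if (mean_amplitude <= 0) stop_config("mean_amplitude must be positive")
  if (duration <= 0) stop_config("duration must be positive")
  if (asymmetry <= 0 || asymmetry >= 1) stop_config("asymmetry must be in (0, 1)")
  if (period_jitter_cv < 0 || amplitude_jitter_cv < 0) {
    stop_config("jitter coefficients must be >= 0")
  }
  if (drift_period <= 0) stop_config("drift_period must be positive")
  structure(list(mean_period = mean_period,
                 period_jitter_cv = period_jitter_cv,
                 mean_amplitude = mean_amplitude,
                 amplitude_jitter_cv = amplitude_jitter_cv,
                 asymmetry = asymmetry,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period,
                 deep_breath_rate = deep_breath_rate,
                 deep_breath_scale = deep_breath_scale,
                 duration = duration,
                 seed = as.integer(seed)),
            class = "breathing_config")
}

#' Sensor model configuration
#'
#' Physical model of the two IMU nodes and the optical reference system.
#' Breathing displacement tilts each node about its x-axis with a linear gain
#' (rad per cm of abdominal displacement); gravity and the world-z linear
#' acceleration are projected through that tilt onto the sensor axes.
#' The sternum node is additionally mounted with a fixed yaw rotation so the
#' tilt-projected gravity component splits across its x and y accelerometer
#' channels.
#'
#' @param accel_fs accelerometer sampling rate, Hz.
#' @param gyro_fs gyroscope sampling rate, Hz.
#' @param accel_noise_sd accelerometer white-noise sd, m/s^2.
#' @param gyro_noise_sd gyroscope white-noise sd, rad/s.
#' @param tilt_gain_node1 sternum-node tilt per displacement, rad/cm.
#' @param tilt_gain_node2 abdomen-node tilt per displacement, rad/cm.
#' @param sternum_yaw fixed mounting rotation of the sternum node about its
#'   z-axis, rad.
#' @param reference_fs sampling rate of the reference respiration signal, Hz.
#' @param reference_noise_sd additive noise sd of the reference signal, cm.
#' @param marker_gain scale between abdominal displacement and the reference
#'   marker's displacement (dimensionless).
#' @param gravity gravitational acceleration, m/s^2.
#'
#' @return an object of class `sensor_config`.
#' @export
sensor_config <- function(accel_fs = 500,
                          gyro_fs = 400,
                          accel_noise_sd = 0.003,
                          gyro_noise_sd = 0.002,
                          tilt_gain_node1 = 0.05,
                          tilt_gain_node2 = 0.02,
                          sternum_yaw = 0.4,
                          reference_fs = 25,
                          reference_noise_sd = 0.02,
                          marker_gain = 1,
                          gravity = 9.81) {
  if (accel_fs <= 0 || gyro_fs <= 0 || reference_fs <= 0) {
    stop_config("sampling rates must be positive")
  }
  if (accel_noise_sd < 0 || gyro_noise_sd < 0 || reference_noise_sd < 0) {
    stop_config("noise standard deviations must be >= 0")
  }
  structure(list(accel_fs = accel_fs, gyro_fs = gyro_fs,
                 accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
                 tilt_gain_node1 = tilt_gain_node1,
                 tilt_gain_node2 = tilt_gain_node2,
                 sternum_yaw = sternum_yaw,
                 reference_fs = reference_fs,
                 reference_noise_sd = reference_noise_sd,
                 marker_gain = marker_gain, gravity = gravity),
            class = "sensor_config")
}

# log-normal draws parameterised by arithmetic mean and coefficient of
# variation; cv = 0 degenerates to the constant mean.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate ground-truth breathing displacement
#'
#' Draws per-cycle periods and amplitudes, assembles the piecewise
#' raised-cosine displacement (plus baseline drift), and returns the ground
#' truth together with end-expiration triggers (one at every trough) and
#' per-cycle validity flags. Deep-breath cycles are flagged invalid,
#' emulating a reference system's cycle rejection.
#'
#' @param config a [breathing_config()].
#' @param grid_fs sampling rate of the returned ground-truth grid, Hz.
#'
#' @return an object of class `ground_truth`: a list with `time` (s),
#'   `displacement` (cm), `triggers` (s, strictly increasing, one per trough),
#'   `cycle_validity` (logical, one per trigger-to-trigger interval),
#'   `duration` (s, actual record length) and the internal cycle table used by
#'   [breathing_displacement()] for closed-form evaluation at any time.
#' @export
#' @examples
#' gt <- generate_breathing(breathing_config(duration = 60, seed = 7))
#' length(gt$triggers) - 1L == length(gt$cycle_validity)
generate_breathing <- function(config, grid_fs = 100) {
  stopifnot(inherits(config, "breathing_config"))
  set.seed(config$seed)
  # draw generously, then keep cycles until the requested duration is covered
  n_guess <- ceiling(config$duration / config$mean_period * 1.5) + 10L
  repeat {
    periods <- rlnorm_mean_cv(n_guess, config$mean_period, config$period_jitter_cv)
    if (sum(periods) >= config$duration) break
    n_guess <- n_guess * 2L
  }
  n_cycles <- which(cumsum(periods) >= config$duration)[1L]
  periods <- periods[seq_len(n_cycles)]
  amplitudes <- rlnorm_mean_cv(n_cycles, config$mean_amplitude,
                               config$amplitude_jitter_cv)
  p_deep <- pmin(1, config$deep_breath_rate * periods / 60)
  deep <- rbinom(n_cycles, 1L, p_deep) == 1L
  amplitudes[deep] <- amplitudes[deep] * config$deep_breath_scale

  starts <- c(0, cumsum(periods))
  duration <- starts[n_cycles + 1L]
  gt <- structure(list(
    cycles = data.frame(start = starts[seq_len(n_cycles)],
                        period = periods, amplitude = amplitudes,
                        deep = deep),
    asymmetry = config$asymmetry,
    drift_amplitude = config$drift_amplitude,
    drift_period = config$drift_period,
    triggers = starts,
    cycle_validity = !deep,
    duration = duration,
    seed = config$seed
  ), class = "ground_truth")
  gt$time <- seq(0, duration, by = 1 / grid_fs)
  gt$displacement <- breathing_displacement(gt, gt$time)
  gt
}

#' Evaluate ground-truth displacement and its derivatives
#'
#' Closed-form evaluation of the piecewise raised-cosine displacement (cm),
#' velocity (cm/s) or acceleration (cm/s^2) at arbitrary times, so sensor
#' streams can be synthesised on any grid without interpolation error.
#'
#' @param gt a `ground_truth` object from [generate_breathing()].
#' @param t numeric vector of times, s.
#' @param deriv 0 (position), 1 (velocity) or 2 (acceleration).
#' @return numeric vector, same length as `t`.
#' @export
breathing_displacement <- function(gt, t, deriv = 0) {
  stopifnot(inherits(gt, "ground_truth"), deriv %in% 0:2)
  cyc <- gt$cycles
  idx <- findInterval(t, c(cyc$start, gt$duration),
                      rightmost.closed = TRUE, all.inside = TRUE)
  A <- cyc$amplitude[idx]
  T_c <- cyc$period[idx]
  u <- (t - cyc$start[idx]) / T_c
  a <- gt$asymmetry
  rise <- u < a
  out <- numeric(length(t))
  # inspiration: 0 -> A over fraction a; expiration: A -> 0 over (1 - a)
  k_r <- pi / (a * T_c)          # rad/s within the rise
  k_f <- pi / ((1 - a) * T_c)    # rad/s within the fall
  ph_r <- pi * u / a
  ph_f <- pi * (u - a) / (1 - a)
  if (deriv == 0) {
    out[rise] <- (A[rise] / 2) * (1 - cos(ph_r[rise]))
    out[!rise] <- (A[!rise] / 2) * (1 + cos(ph_f[!rise]))
  } else if (deriv == 1) {
    out[rise] <- (A[rise] / 2) * k_r[rise] * sin(ph_r[rise])
    out[!rise] <- -(A[!rise] / 2) * k_f[!rise] * sin(ph_f[!rise])
  } else {
    out[rise] <- (A[rise] / 2) * k_r[rise]^2 * cos(ph_r[rise])
    out[!rise] <- -(A[!rise] / 2) * k_f[!rise]^2 * cos(ph_f[!rise])
  }
  if (gt$drift_amplitude != 0) {
    w <- 2 * pi / gt$drift_period
    out <- out + switch(as.character(deriv),
      "0" = gt$drift_amplitude * sin(w * t),
      "1" = gt$drift_amplitude * w * cos(w * t),
      "2" = -gt$drift_amplitude * w^2 * sin(w * t))
  }
  out
}

#' Simulate one IMU node
#'
#' Projects gravity plus the world-z linear acceleration of the breathing
#' motion through the node's breathing-correlated tilt about its x-axis and
#' adds white sensor noise. Accelerometer and gyroscope streams are sampled
#' on their own grids. The noise stream is seeded deterministically from the
#' ground truth's seed and the node role, so a given ground truth always
#' yields bit-identical recordings.
#'
#' @param gt a `ground_truth` object.
#' @param node_role `"sternum"` (node 1) or `"abdomen"` (node 2).
#' @param config a [sensor_config()].
#' @return a [node_recording()].
#' @export
simulate_node <- function(gt, node_role = c("sternum", "abdomen"),
                          config = sensor_config()) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "sensor_config"))
  node_role <- tryCatch(match.arg(node_role),
                        error = function(e) stop_config("unknown node_role"))
  gain <- if (node_role == "sternum") config$tilt_gain_node1 else config$tilt_gain_node2
  yaw <- if (node_role == "sternum") config$sternum_yaw else 0
  set.seed(gt$seed + if (node_role == "sternum") 1001L else 1002L)

  t_a <- seq(0, gt$duration, by = 1 / config$accel_fs)
  disp_a <- breathing_displacement(gt, t_a)                # cm
  acc_z_world <- 0.01 * breathing_displacement(gt, t_a, 2) # m/s^2
  theta <- gain * disp_a                                   # rad
  f_total <- config$gravity + acc_z_world                  # specific force, world z
  # tilt about x maps world-z specific force onto sensor y (sin) and z (cos);
  # the mounting yaw then splits the y component across x' and y'
  f_y <- f_total * sin(theta)
  f_z <- f_total * cos(theta)
  accel <- cbind(ax = sin(yaw) * f_y, ay = cos(yaw) * f_y, az = f_z)
  if (config$accel_noise_sd > 0) {
    accel <- accel + matrix(rnorm(length(accel), 0, config$accel_noise_sd),
                            ncol = 3)
  }

  t_g <- seq(0, gt$duration, by = 1 / config$gyro_fs)
  theta_dot <- gain * breathing_displacement(gt, t_g, 1)   # rad/s
  gyro <- cbind(gx = cos(yaw) * theta_dot, gy = -sin(yaw) * theta_dot,
                gz = numeric(length(t_g)))
  if (config$gyro_noise_sd > 0) {
    gyro <- gyro + matrix(rnorm(length(gyro), 0, config$gyro_noise_sd),
                          ncol = 3)
  }

  node_recording(node_id = if (node_role == "sternum") 1L else 2L,
                 accel_time = t_a, accel = accel,
                 gyro_time = t_g, gyro = gyro)
}

#' Simulate the optical reference respiration signal
#'
#' The reference marker is assumed to ride on the abdominal displacement with
#' a configurable gain; its signal is the scaled ground-truth displacement
#' sampled at the reference rate plus white noise. The ground truth's
#' end-expiration triggers and cycle-validity flags are carried over.
#'
#' @param gt a `ground_truth` object.
#' @param config a [sensor_config()].
#' @return a [respiration_signal()] of kind `"reference"` (cm), with
#'   attributes `triggers` and `cycle_validity`.
#' @export
simulate_reference <- function(gt, config = sensor_config()) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "sensor_config"))
  set.seed(gt$seed + 1003L)
  t_r <- seq(0, gt$duration, by = 1 / config$reference_fs)
  v <- config$marker_gain * breathing_displacement(gt, t_r)
  if (config$reference_noise_sd > 0) {
    v <- v + rnorm(length(v), 0, config$reference_noise_sd)
  }
  sig <- respiration_signal(t_r, v, unit = "cm", kind = "reference")
  attr(sig, "triggers") <- gt$triggers
  attr(sig, "cycle_validity") <- gt$cycle_validity
  sig
}
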