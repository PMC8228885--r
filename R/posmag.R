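#' Initialise the orientation filter from a static accelerometer sample
#'
#' Builds the shortest-arc quaternion that rotates the measured specific-force
#' direction onto world z (yaw is unobservable from gravity and set to zero).
#' Gives the filter a near-converged start for a supine subject.
#'
#' @param accel a 3-vector, m/s^2.
#' @param beta gradient gain of the filter.
#' @return an `orientation_state`: list with `quaternion` (unit 4-vector
#'   w, x, y, z; sensor to world) and `beta`.
#' @export
madgwick_init <- function(accel = c(0, 0, 9.81), beta = 0.1) {
  nrm <- sqrt(sum(accel^2))
  if (nrm == 0) {
    q <- c(1, 0, 0, 0)
  } else {
    a <- accel / nrm
    d <- a[3]                       # cos(angle to world z)
    if (d > 1 - 1e-12) {
      q <- c(1, 0, 0, 0)
    } else if (d < -1 + 1e-12) {
      q <- c(0, 1, 0, 0)            # upside down: 180 deg about x
    } else {
      axis <- c(a[2], -a[1], 0)     # cross(a, z)
      axis <- axis / sqrt(sum(axis^2))
      ang <- acos(d)
      q <- c(cos(ang / 2), sin(ang / 2) * axis)
    }
  }
  structure(list(quaternion = q, beta = beta), class = "orientation_state")
}

#' Single orientation-filter update
#'
#' Advances the quaternion by one sample: gyroscope integration minus the
#' beta-scaled normalised gradient of the gravity-alignment objective
#' (6-axis variant, no magnetometer), then renormalisation. Mostly useful for
#' testing; [world_z_acceleration()] runs the whole record in compiled code.
#'
#' @param state an `orientation_state` from [madgwick_init()].
#' @param gyro 3-vector of angular rates, rad/s.
#' @param accel 3-vector of specific force, m/s^2 (a zero vector skips the
#'   gradient step).
#' @param dt time step, s.
#' @return the updated `orientation_state`.
#' @export
madgwick_update <- function(state, gyro, accel, dt) {
  stopifnot(inherits(state, "orientation_state"))
  if (dt <= 0) stop_config("dt must be positive")
  q <- madgwick_filter_cpp(matrix(gyro, 1), matrix(accel, 1), dt,
                           state$beta, state$quaternion)
  state$quaternion <- as.numeric(q[1, ])
  state
}

# rotate sensor-frame vectors (rows of m) into the world frame by the
# per-sample quaternions (rows of q, as w,x,y,z); returns only the world-z
# component, the one the respiration estimate needs.
quat_rotate_z <- function(q, m) {
  2 * (q[, 2] * q[, 4] - q[, 1] * q[, 3]) * m[, 1] +
    2 * (q[, 3] * q[, 4] + q[, 1] * q[, 2]) * m[, 2] +
    (1 - 2 * (q[, 2]^2 + q[, 3]^2)) * m[, 3]
}

#' World-frame vertical acceleration of the abdomen node
#'
#' Runs the orientation filter over the abdomen node's resampled gyroscope
#' and accelerometer streams and rotates each measured specific-force vector
#' into the world frame, returning its vertical (z, up) component. For a
#' static sensor this converges to `g` regardless of tilt.
#'
#' @param rec a [resample_to_grid()] record.
#' @param params an [algorithm_params()].
#' @return numeric vector of world-z specific force, m/s^2.
#' @export
world_z_acceleration <- function(rec, params = algorithm_params()) {
  stopifnot(inherits(rec, "resampled_record"))
  state <- madgwick_init(rec$node2_accel_xyz[1, ], params$madgwick_beta)
  q <- madgwick_filter_cpp(rec$node2_gyro_xyz, rec$node2_accel_xyz,
                           1 / rec$fs, params$madgwick_beta, state$quaternion)
  quat_rotate_z(q, rec$node2_accel_xyz)
}

#' Respiratory acceleration: remove gravity
#'
#' @param a_z world-z specific force, m/s^2.
#' @param g gravitational acceleration, m/s^2.
#' @return `a_z - g`, elementwise.
#' @export
respiratory_acceleration <- function(a_z, g = 9.81) a_z - g

# steady-state initial conditions for a unit step input, so the
# forward-backward filter starts settled at the signal's edge value
# (companion-matrix construction).
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  comp_t <- rbind(-a[-1] / a[1], cbind(diag(1, nf - 2), 0))
  solve(diag(nf - 1) - t(comp_t), b[-1] - a[-1] * b[1])
}

# zero-phase forward-backward application of an IIR filter, with
# odd-reflection edge padding of length 3 x filter order and steady-state
# initial conditions at each pass.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  nf <- max(length(a), length(b))
  padlen <- 3L * (nf - 1L)
  if (n <= padlen) stop_data("signal shorter than the filter warm-up length")
  ext <- c(2 * x[1] - x[(padlen + 1L):2], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Integrate a signal and high-pass filter the result
#'
#' Numerically integrates by a time-weighted cumulative sum (the integral is
#' taken to start at zero) and removes the unknown integration constant and
#' low-frequency drift with a zero-phase (forward-backward) second-order
#' Butterworth high-pass filter at cutoff `f_b`.
#'
#' Note the zero-phase filter applies the Butterworth magnitude response
#' twice, so a sinusoid at frequency `f` keeps a fraction
#' `1 / (1 + (f_b/f)^4)` of its amplitude per call.
#'
#' @param x numeric samples (e.g. m/s^2 to get m/s).
#' @param fs sampling rate, Hz.
#' @param f_b high-pass cutoff, Hz (must be below `fs/2`).
#' @return the filtered integral, same length as `x`.
#' @export
integrate_highpass <- function(x, fs, f_b = 0.2) {
  if (f_b >= fs / 2) stop_config("f_b must be below the Nyquist frequency")
  dt <- 1 / fs
  y <- c(0, dt * cumsum(x[-1]))
  bw <- signal::butter(2, f_b / (fs / 2), type = "high")
  zero_phase_filter(bw$b, bw$a, y)
}

#' Compute the polarity-and-magnitude position signal p(t)
#'
#' Chains orientation estimation, gravity removal, and two
#' integrate-plus-high-pass stages to produce the abdomen node's vertical
#' displacement. The result carries the physical polarity and a centimetre
#' scale; periodic motion is recovered up to the (known) high-pass
#' attenuation, while a pause in motion decays towards zero.
#'
#' @param rec a [resample_to_grid()] record.
#' @param params an [algorithm_params()].
#' @return a [respiration_signal()] of kind `"polmag"`, unit cm.
#' @export
compute_polmag_signal <- function(rec, params = algorithm_params()) {
  a_resp <- respiratory_acceleration(world_z_acceleration(rec, params),
                                     params$g)
  vel <- integrate_highpass(a_resp, rec$fs, params$f_b)
  pos <- integrate_highpass(vel, rec$fs, params$f_b)
  respiration_signal(rec$time, 100 * pos, unit = "cm", kind = "polmag")
}
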