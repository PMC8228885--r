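#' Algorithm parameters for the respiration estimation pipeline
#'
#' Bundles every tunable of the estimation pipeline. The defaults reproduce
#' the parameter set used throughout the package's validation: all window
#' lengths are derived from the common sampling rate `fs`.
#'
#' @param fs common analysis sampling rate in Hz (all streams are resampled
#'   onto this grid).
#' @param w_avg_s shape-signal moving-average window, samples
#'   (default `floor(0.8 * fs)`).
#' @param n_circ number of samples used to fit the PCA basis
#'   (default `floor(60 * fs)`, i.e. the first 60 s).
#' @param g gravitational acceleration, m/s^2.
#' @param f_b high-pass cutoff frequency for the integration stages, Hz.
#' @param w_avg_f1 fusion window for the shape-signal moving average, samples
#'   (default `floor(10 * fs)`).
#' @param w_avg_f2 fusion window for the moving variances, samples
#'   (default `floor(60 * fs)`).
#' @param w_avg_f3 baseline-estimation moving-average window, samples
#'   (default `floor(60 * fs)`).
#' @param d_max maximum delay searched when synchronising the shape and
#'   position signals, seconds.
#' @param madgwick_beta gain of the orientation filter's accelerometer
#'   correction step (dimensionless).
#'
#' @return an object of class `algorithm_params` (a named list).
#' @export
#' @examples
#' p <- algorithm_params()
#' p$w_avg_s  # 80 samples at fs = 100
algorithm_params <- function(fs = 100,
                             w_avg_s = floor(0.8 * fs),
                             n_circ = floor(60 * fs),
                             g = 9.81,
                             f_b = 0.2,
                             w_avg_f1 = floor(10 * fs),
                             w_avg_f2 = floor(60 * fs),
                             w_avg_f3 = floor(60 * fs),
                             d_max = 2,
                             madgwick_beta = 0.1) {
  if (fs <= 0) stop_config("fs must be positive")
  if (f_b <= 0 || f_b >= fs / 2) stop_config("f_b must lie in (0, fs/2)")
  if (w_avg_s < 1 || n_circ < 2) stop_config("window lengths too short")
  if (d_max <= 0) stop_config("d_max must be positive")
  structure(list(fs = fs, w_avg_s = w_avg_s, n_circ = n_circ, g = g,
                 f_b = f_b, w_avg_f1 = w_avg_f1, w_avg_f2 = w_avg_f2,
                 w_avg_f3 = w_avg_f3, d_max = d_max,
                 madgwick_beta = madgwick_beta),
            class = "algorithm_params")
}

#' @export
print.algorithm_params <- function(x, ...) {
  cat("Respiration estimation parameters (fs =", x$fs, "Hz)\n")
  cat("  shape:   w_avg_s =", x$w_avg_s, " n_circ =", x$n_circ, "\n")
  cat("  posmag:  g =", x$g, " f_b =", x$f_b, "Hz  beta =", x$madgwick_beta, "\n")
  cat("  fusion:  w_avg_f1/2/3 =", x$w_avg_f1, x$w_avg_f2, x$w_avg_f3,
      " d_max =", x$d_max, "s\n")
  invisible(x)
}

#' Amplitude-gating configuration
#'
#' @param q_low,q_high quantile levels defining the global gating thresholds;
#'   samples with respiration amplitude outside the closed interval
#'   `[quantile(q_low), quantile(q_high)]` are rejected.
#' @param n_gates number of equidistant amplitude gates between the thresholds.
#'
#' @return an object of class `gating_config`.
#' @export
gating_config <- function(q_low = 0.2, q_high = 0.8, n_gates = 5) {
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1)) {
    stop_config("need 0 <= q_low < q_high <= 1")
  }
  if (n_gates < 1) stop_config("n_gates must be >= 1")
  structure(list(q_low = q_low, q_high = q_high, n_gates = as.integer(n_gates)),
            class = "gating_config")
}
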