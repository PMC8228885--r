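as_values <- function(x) if (inherits(x, "respiration_signal")) x$value else as.numeric(x)

#' Estimate the delay between the shape and position signals
#'
#' The zero-phase high-pass filtering of the position signal and the causal
#' moving average of the shape signal leave an unknown relative delay of
#' either sign. It is found by maximising the magnitude of the lagged
#' correlation over the mid-half of the record, scanning every grid delay in
#' `[-d_max, d_max]`; the shape signal's polarity is arbitrary, so only the
#' correlation's magnitude identifies the alignment, and its sign at the
#' chosen lag is read off separately by [estimate_polarity()]. Ties are
#' broken towards the smallest delay magnitude, negative first.
#'
#' @param s shape signal (vector or [respiration_signal()]).
#' @param p position signal on the same grid.
#' @param fs sampling rate, Hz.
#' @param d_max maximum absolute delay searched, s.
#' @return the delay `d` in seconds (positive when `p` lags `s`... i.e. the
#'   correlation of `s(t)` with `p(t + d)` is maximal).
#' @export
estimate_delay <- function(s, p, fs, d_max = 2) {
  s <- as_values(s); p <- as_values(p)
  n <- length(s)
  if (length(p) != n) stop_data("signals must share one grid")
  if (n <= 4 * d_max * fs) stop_data("record too short for delay search")
  idx <- (floor(n / 4) + 1L):floor(3 * n / 4)
  kk <- -round(d_max * fs):round(d_max * fs)
  corr <- vapply(kk, function(k) {
    j <- idx + k
    ok <- j >= 1L & j <= n
    sum(s[idx[ok]] * p[j[ok]])
  }, numeric(1))
  # tie-break: smallest |d| first, then negative before positive
  ord <- order(abs(kk), kk)
  best <- ord[which.max(abs(corr[ord]))]
  kk[best] / fs
}

#' Estimate the polarity of the respiration signal
#'
#' Sign of the mid-half correlation between the shape signal and the
#' delay-aligned position signal. A zero correlation defaults to +1.
#'
#' @inheritParams estimate_delay
#' @param d delay from [estimate_delay()], s.
#' @return `+1` or `-1`.
#' @export
estimate_polarity <- function(s, p, d, fs) {
  s <- as_values(s); p <- as_values(p)
  n <- length(s)
  idx <- (floor(n / 4) + 1L):floor(3 * n / 4)
  k <- round(d * fs)
  j <- idx + k
  ok <- j >= 1L & j <= n
  cc <- sum(s[idx[ok]] * p[j[ok]])
  if (cc < 0) -1 else 1
}

#' Sliding-window mean and variance by incremental updates
#'
#' Trailing-window moving statistics over the `min(w, i)` most recent
#' samples, maintained by Welford-style add/remove updates (one pass, O(1)
#' per sample). The variance is the population variance of the window.
#'
#' @param x numeric vector.
#' @param w window length in samples (`>= 2`).
#' @return list with numeric vectors `avg` and `var`, same length as `x`.
#' @export
moving_stats <- function(x, w) {
  if (w < 2) stop_config("moving_stats window must be >= 2")
  w <- as.integer(w)
  n <- length(x)
  avg <- numeric(n); va <- numeric(n)
  m <- 0; M2 <- 0; cnt <- 0L
  for (i in seq_len(n)) {
    xi <- x[i]
    cnt <- cnt + 1L
    d <- xi - m
    m <- m + d / cnt
    M2 <- M2 + d * (xi - m)
    if (cnt > w) {
      xo <- x[i - w]
      cnt <- cnt - 1L
      d <- xo - m
      m <- m - d / cnt
      M2 <- M2 - d * (xo - m)
    }
    avg[i] <- m
    va[i] <- max(M2, 0) / cnt
  }
  list(avg = avg, var = va)
}

#' Fuse shape and position signals (without baseline correction)
#'
#' Rescales the mean-centred shape signal to the position signal's local
#' amplitude by the square root of the running variance ratio, with the
#' polarity `q` resolving the arbitrary PCA sign:
#' `r_wobc(t) = q * sqrt(p_var(t) / s_var(t)) * (s(t) - s_avg(t))`.
#' Where the shape variance is numerically zero the scale factor is held at
#' its last valid value.
#'
#' @param s shape signal values.
#' @param p_aligned delay-aligned position signal values, cm.
#' @param q polarity, +1 or -1.
#' @param params an [algorithm_params()] (windows `w_avg_f1` for the mean,
#'   `w_avg_f2` for the variances).
#' @return list with `r_wobc` (cm) and the per-sample diagnostics
#'   `s_avg`, `s_var`, `p_avg`, `p_var`, `scale`.
#' @export
fuse_wobc <- function(s, p_aligned, q, params = algorithm_params()) {
  s <- as_values(s); p_aligned <- as_values(p_aligned)
  st_s1 <- moving_stats(s, params$w_avg_f1)
  st_s2 <- moving_stats(s, params$w_avg_f2)
  st_p <- moving_stats(p_aligned, params$w_avg_f2)
  ok <- st_s2$var >= 1e-12
  if (!any(ok)) stop_degenerate("shape signal has no variance")
  scale <- sqrt(st_p$var / pmax(st_s2$var, 1e-12))
  # hold the scale at its last valid value across degenerate stretches
  # (leading degenerate samples take the first valid value)
  if (!all(ok)) {
    valid_idx <- which(ok)
    last_valid <- cummax(ifelse(ok, seq_along(ok), 0L))
    last_valid[last_valid == 0L] <- valid_idx[1L]
    scale <- scale[last_valid]
  }
  list(r_wobc = q * scale * (s - st_s1$avg),
       s_avg = st_s1$avg, s_var = st_s2$var,
       p_avg = st_p$avg, p_var = st_p$var, scale = scale)
}

#' Estimate baseline drift from the shape signal
#'
#' The position signal is high-pass filtered and carries no baseline
#' information, so slow drift is taken from the shape signal: its trailing
#' moving average (window `w_avg_f3`), centred by the global mean and mapped
#' to the fused signal's scale by the ratio of global standard deviations:
#' `b(t) = (mavg(s, w_avg_f3) - mean(s)) * sd(r_wobc) / sd(s)`.
#'
#' @param s shape signal values.
#' @param r_wobc fused signal before baseline correction, cm.
#' @param params an [algorithm_params()].
#' @return per-sample baseline estimate, cm.
#' @export
estimate_baseline <- function(s, r_wobc, params = algorithm_params()) {
  s <- as_values(s); r_wobc <- as_values(r_wobc)
  if (length(s) <= params$w_avg_f3) stop_data("record shorter than w_avg_f3")
  sd_r <- sd(r_wobc)
  sd_s <- sd(s)
  if (!is.finite(sd_r) || sd_r == 0 || sd_s == 0) {
    stop_degenerate("degenerate signal: zero variance")
  }
  (moving_average(s, params$w_avg_f3) - mean(s)) * sd_r / sd_s
}

#' Apply the polarity-weighted baseline correction
#'
#' @param r_wobc fused signal before correction, cm.
#' @param b baseline estimate from [estimate_baseline()], cm.
#' @param q polarity, +1 or -1.
#' @return `r_wobc + q * b`, elementwise.
#' @export
baseline_correct <- function(r_wobc, b, q) as_values(r_wobc) + q * as_values(b)

#' Calibrate the fused signal's amplitude against a reference
#'
#' Computes the subject-specific positive constant
#' `gamma = mean(reference cycle magnitudes) / mean(estimated cycle
#' magnitudes)` and rescales the fused signal so the two mean cycle
#' magnitudes agree exactly. Quantile-based amplitude gating is invariant to
#' this scaling; calibration matters when the estimate must stand in for the
#' reference signal in physical units.
#'
#' @param r the fused [respiration_signal()] (cm).
#' @param ref_cycles,est_cycles [cycle_table()]s for the reference and the
#'   estimate, built from the same triggers.
#' @return list with `r_cal` (calibrated [respiration_signal()]) and `gamma`.
#' @export
calibrate_amplitude <- function(r, ref_cycles, est_cycles) {
  stopifnot(inherits(ref_cycles, "cycle_table"), inherits(est_cycles, "cycle_table"))
  m_est <- mean_cycle_magnitude(est_cycles)
  if (m_est <= 0) stop_degenerate("estimated cycle magnitude is zero")
  gamma <- mean_cycle_magnitude(ref_cycles) / m_est
  r_cal <- r
  r_cal$value <- gamma * r_cal$value
  list(r_cal = r_cal, gamma = gamma)
}

# shift a vector by k samples (positive k pulls later samples earlier,
# x_out[i] = x[i + k]); edges hold the first/last value.
shift_samples <- function(x, k) {
  n <- length(x)
  j <- pmin(pmax(seq_len(n) + k, 1L), n)
  x[j]
}

#' Full respiration estimation pipeline
#'
#' Runs the complete fusion chain on a resampled two-node record: shape
#' signal, position signal, delay synchronisation, polarity, variance-ratio
#' rescaling, and baseline correction.
#'
#' @param rec a [resample_to_grid()] record.
#' @param params an [algorithm_params()].
#' @return an object of class `respiration_estimate`: list with `r` (fused
#'   [respiration_signal()], cm), `shape`, `polmag` (component signals) and
#'   `diagnostics` (delay `d` in s, polarity `q`, `gamma` (NA until
#'   [calibrate_amplitude()] is applied), per-sample moving statistics and
#'   baseline `b`).
#' @export
estimate_respiration <- function(rec, params = algorithm_params()) {
  shape <- compute_shape_signal(rec, params)
  polmag <- compute_polmag_signal(rec, params)
  d <- estimate_delay(shape$value, polmag$value, rec$fs, params$d_max)
  q <- estimate_polarity(shape$value, polmag$value, d, rec$fs)
  p_aligned <- shift_samples(polmag$value, round(d * rec$fs))
  fw <- fuse_wobc(shape$value, p_aligned, q, params)
  b <- estimate_baseline(shape$value, fw$r_wobc, params)
  r <- baseline_correct(fw$r_wobc, b, q)
  structure(list(
    r = respiration_signal(rec$time, r, unit = "cm", kind = "fused"),
    shape = shape, polmag = polmag,
    diagnostics = list(d = d, q = q, gamma = NA_real_,
                       s_avg = fw$s_avg, s_var = fw$s_var,
                       p_avg = fw$p_avg, p_var = fw$p_var,
                       scale = fw$scale, b = b)
  ), class = "respiration_estimate")
}

#' @export
print.respiration_estimate <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("respiration estimate: %d samples, d = %+.2f s, q = %+d%s\n",
              nrow(x$r), d$d, d$q,
              if (is.na(d$gamma)) "" else sprintf(", gamma = %.3f", d$gamma)))
  invisible(x)
}

#' Write a fused respiration signal and its diagnostics
#'
#' Writes `r.csv` (`t, value_cm`) and a JSON sidecar with the scalar
#' diagnostics (`d`, `q`, `gamma`).
#'
#' @param est a `respiration_estimate`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(est, path) {
  stopifnot(inherits(est, "respiration_estimate"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(t = est$r$time, value_cm = est$r$value),
            file.path(path, "r.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(d = est$diagnostics$d, q = est$diagnostics$q,
         gamma = est$diagnostics$gamma),
    file.path(path, "diagnostics.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}
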