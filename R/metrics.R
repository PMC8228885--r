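#' Per-cycle summary of a respiration signal
#'
#' @param peak_times inspiration-peak times, s (strictly increasing).
#' @param durations cycle durations, s (`diff(peak_times)`).
#' @param magnitudes cycle magnitudes, cm (max - min between consecutive
#'   peaks).
#' @param source `"estimate"` or `"reference"`.
#' @return an object of class `cycle_table` (a data.frame of the per-cycle
#'   quantities; `peak_times` keeps one more entry than the cycle columns and
#'   is stored as an attribute).
#' @export
cycle_table <- function(peak_times, durations, magnitudes,
                        source = c("estimate", "reference")) {
  source <- match.arg(source)
  if (is.unsorted(peak_times, strictly = TRUE)) {
    stop_data("peak times must be strictly increasing")
  }
  if (length(durations) != length(peak_times) - 1L ||
      length(magnitudes) != length(durations)) {
    stop_data("need one duration and magnitude per consecutive peak pair")
  }
  if (any(durations <= 0) || any(magnitudes < 0)) {
    stop_data("durations must be positive and magnitudes non-negative")
  }
  structure(data.frame(duration = durations, magnitude = magnitudes),
            peak_times = peak_times, source = source,
            class = c("cycle_table", "data.frame"))
}

#' @export
print.cycle_table <- function(x, ...) {
  cat(sprintf("%s cycle table: %d cycles, mean duration %.2f s, mean magnitude %.2f cm\n",
              attr(x, "source"), nrow(x), mean(x$duration), mean(x$magnitude)))
  invisible(x)
}

#' Find per-cycle inspiration peak times
#'
#' Within each window between consecutive end-expiration triggers, collects
#' the local maxima of the signal (sign change of the first discrete
#' difference from positive to non-positive) and takes the time of the
#' largest one; a window with no local maximum (e.g. a monotone stretch)
#' falls back to the window's argmax. Windows are half-open
#' `[trigger_i, trigger_{i+1})`.
#'
#' @param r a [respiration_signal()].
#' @param triggers end-expiration trigger times, s (strictly increasing).
#' @return numeric vector of peak times, one per trigger-to-trigger window.
#' @export
peak_inspiration_times <- function(r, triggers) {
  stopifnot(inherits(r, "respiration_signal"))
  if (length(triggers) < 2) stop_data("need at least two triggers")
  if (is.unsorted(triggers, strictly = TRUE)) {
    stop_data("triggers must be strictly increasing")
  }
  v <- r$value; tt <- r$time
  n <- length(v)
  dv <- diff(v)
  # local max at j: rising into j, not rising out of j
  is_max <- c(FALSE, dv > 0) & c(dv <= 0, FALSE)
  vapply(seq_len(length(triggers) - 1L), function(i) {
    w <- which(tt >= triggers[i] & tt < triggers[i + 1L])
    if (length(w) == 0) stop_data("a trigger window holds no samples")
    cand <- w[is_max[w]]
    if (length(cand) == 0) cand <- w
    tt[cand[which.max(v[cand])]]
  }, numeric(1))
}

#' Cycle durations from peak times
#' @param peaks inspiration peak times, s.
#' @return `diff(peaks)`, s.
#' @export
cycle_durations <- function(peaks) {
  if (length(peaks) < 2) stop_data("need at least two peaks")
  diff(peaks)
}

#' Cycle magnitudes between consecutive peaks
#' @param r a [respiration_signal()].
#' @param peaks inspiration peak times, s.
#' @return max - min of the signal over each closed peak-to-peak interval.
#' @export
cycle_magnitudes <- function(r, peaks) {
  stopifnot(inherits(r, "respiration_signal"))
  if (length(peaks) < 2) stop_data("need at least two peaks")
  vapply(seq_len(length(peaks) - 1L), function(i) {
    w <- r$value[r$time >= peaks[i] & r$time <= peaks[i + 1L]]
    max(w) - min(w)
  }, numeric(1))
}

#' Build a cycle table for a signal from shared triggers
#'
#' Convenience wrapper: peak detection, durations and magnitudes in one call.
#' Tables built from the same trigger list always pair cycle-for-cycle.
#'
#' @inheritParams peak_inspiration_times
#' @param source table label, `"estimate"` or `"reference"`.
#' @return a [cycle_table()].
#' @export
detect_cycles <- function(r, triggers, source = c("estimate", "reference")) {
  peaks <- peak_inspiration_times(r, triggers)
  cycle_table(peaks, cycle_durations(peaks), cycle_magnitudes(r, peaks),
              source = match.arg(source))
}

#' Mean absolute breathing-rate error per minute
#'
#' Sums the per-cycle relative duration errors and normalises by the
#' measurement duration in minutes (the conventional unit of this statistic
#' is 1/min).
#'
#' @param d_est,d_ref paired cycle-duration vectors, s.
#' @param t_min measurement duration in minutes.
#' @return the error statistic, 1/min.
#' @export
#' @examples
#' mae_breathing_rate(c(5, 3), c(4, 4), t_min = 1)  # 0.5
mae_breathing_rate <- function(d_est, d_ref, t_min) {
  if (length(d_est) != length(d_ref)) stop_data("duration lists must pair up")
  sum(abs(d_est - d_ref) / d_ref) / t_min
}

#' Mean absolute pointwise amplitude error
#'
#' @param r,r_ref signals on the same grid (resample the reference first with
#'   [resample_signal()]).
#' @return mean of `|r - r_ref|`, cm.
#' @export
mae_amplitude <- function(r, r_ref) {
  if (inherits(r, "respiration_signal") && inherits(r_ref, "respiration_signal")) {
    if (nrow(r) != nrow(r_ref) || max(abs(r$time - r_ref$time)) > 1e-9) {
      stop_data("signals must share one grid")
    }
  }
  r <- as_values(r); r_ref <- as_values(r_ref)
  if (length(r) != length(r_ref)) stop_data("signals must share one grid")
  mean(abs(r - r_ref))
}

#' Mean cycle magnitude
#' @param x a [cycle_table()] or a numeric vector of magnitudes, cm.
#' @return arithmetic mean, cm.
#' @export
mean_cycle_magnitude <- function(x) {
  m <- if (inherits(x, "cycle_table")) x$magnitude else as.numeric(x)
  if (length(m) == 0) stop_data("no cycles")
  mean(m)
}

#' Resample a signal onto a target grid
#'
#' Linear interpolation of the signal values at the target times (no
#' extrapolation: target times must lie inside the signal's support).
#'
#' @param sig a [respiration_signal()].
#' @param time target times, s.
#' @return a [respiration_signal()] of the same kind on the new grid.
#' @export
resample_signal <- function(sig, time) {
  stopifnot(inherits(sig, "respiration_signal"))
  v <- approx(sig$time, sig$value, xout = time, rule = 2)$y
  out <- respiration_signal(time, v, unit = attr(sig, "unit"),
                            kind = attr(sig, "kind"))
  attr(out, "triggers") <- attr(sig, "triggers")
  attr(out, "cycle_validity") <- attr(sig, "cycle_validity")
  out
}

#' Remove baseline drift from a reference signal
#'
#' Subtracts the signal's own trailing moving average (default window 60 s),
#' removing slow drift while leaving respiration-band amplitude essentially
#' untouched.
#'
#' @param r_ref a reference [respiration_signal()].
#' @param window moving-average window, s.
#' @return the drift-corrected [respiration_signal()].
#' @export
baseline_correct_reference <- function(r_ref, window = 60) {
  stopifnot(inherits(r_ref, "respiration_signal"))
  fs_ref <- 1 / stats::median(diff(r_ref$time))
  w <- max(1L, floor(window * fs_ref))
  out <- r_ref
  out$value <- r_ref$value - moving_average(r_ref$value, w)
  out
}

#' Compare an estimated respiration signal against a reference
#'
#' Builds cycle tables for both signals from the shared end-expiration
#' triggers, then computes the breathing-rate error, the mean cycle
#' magnitudes, and the mean absolute amplitude error (the reference is
#' linearly interpolated onto the estimate's grid).
#'
#' The pointwise amplitude error can be computed on the raw signals
#' (`align = "none"`) or, since the estimate's zero level is arbitrary (it
#' descends from a PCA projection) while a physical reference carries its
#' marker's absolute position, on drift-corrected signals
#' (`align = "baseline"`): both signals have their trailing 60 s moving
#' average removed ([baseline_correct_reference()]) before the mean absolute
#' difference is taken. Cycle durations and magnitudes are offset-invariant
#' and unaffected by the choice.
#'
#' @param r estimated [respiration_signal()], cm.
#' @param r_ref reference [respiration_signal()], cm.
#' @param triggers shared end-expiration trigger times, s.
#' @param q polarity of the estimate (reported, not used in the arithmetic).
#' @param align `"baseline"` (default) or `"none"`, see Details.
#' @return an object of class `comparison_report`: list with `mae_fb`
#'   (1/min), `est_magn`, `ref_magn`, `mae_amplitude` (cm), `n_cycles`, `q`,
#'   and the two [cycle_table()]s.
#' @export
compare_respiration <- function(r, r_ref, triggers, q = NA,
                                align = c("baseline", "none")) {
  align <- match.arg(align)
  cyc_est <- detect_cycles(r, triggers, "estimate")
  cyc_ref <- detect_cycles(r_ref, triggers, "reference")
  t_min <- diff(range(r$time)) / 60
  ref_on_grid <- resample_signal(r_ref, r$time)
  if (align == "baseline") {
    r_cmp <- baseline_correct_reference(r, 60)
    ref_cmp <- baseline_correct_reference(ref_on_grid, 60)
  } else {
    r_cmp <- r
    ref_cmp <- ref_on_grid
  }
  structure(list(
    mae_fb = mae_breathing_rate(cyc_est$duration, cyc_ref$duration, t_min),
    est_magn = mean_cycle_magnitude(cyc_est),
    ref_magn = mean_cycle_magnitude(cyc_ref),
    mae_amplitude = mae_amplitude(r_cmp$value, ref_cmp$value),
    n_cycles = nrow(cyc_est),
    q = q,
    cycles_est = cyc_est, cycles_ref = cyc_ref
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(paste0(
    "respiration comparison over %d cycles:\n",
    "  mean cycle magnitude: estimate %.2f cm, reference %.2f cm\n",
    "  MAE amplitude: %.3f cm\n  MAE breathing rate: %.3f 1/min\n"),
    x$n_cycles, x$est_magn, x$ref_magn, x$mae_amplitude, x$mae_fb))
  invisible(x)
}

#' Serialise a comparison report
#'
#' Writes the scalar metrics to JSON and the per-cycle tables to CSV.
#'
#' @param report a `comparison_report`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    report[c("mae_fb", "est_magn", "ref_magn", "mae_amplitude", "n_cycles", "q")],
    file.path(path, "comparison.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  for (nm in c("cycles_est", "cycles_ref")) {
    write.csv(as.data.frame(report[[nm]]),
              file.path(path, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(path)
}
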