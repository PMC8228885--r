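#' Global amplitude-gating thresholds
#'
#' Empirical quantiles (linear interpolation of order statistics) of the
#' respiration signal over the full record, at the configured lower and
#' upper levels.
#'
#' @param r a [respiration_signal()] or numeric vector.
#' @param config a [gating_config()].
#' @return named numeric vector `c(thr_low, thr_high)`.
#' @export
compute_thresholds <- function(r, config = gating_config()) {
  v <- as_values(r)
  if (length(v) == 0) stop_data("empty signal")
  thr <- quantile(v, c(config$q_low, config$q_high), names = FALSE, type = 7)
  if (thr[1] == thr[2]) {
    warning("degenerate thresholds: signal has no amplitude spread")
  }
  c(thr_low = thr[1], thr_high = thr[2])
}

#' Broadcast per-cycle validity to samples
#'
#' Samples inside a trigger-to-trigger interval inherit that cycle's validity
#' flag; samples before the first or after the last trigger belong to no
#' cycle and are invalid.
#'
#' @param time sample times, s.
#' @param triggers end-expiration trigger times, s.
#' @param cycle_validity logical, one flag per trigger-to-trigger interval.
#' @return logical vector, one flag per sample.
#' @export
cycle_validity_mask <- function(time, triggers, cycle_validity) {
  if (length(cycle_validity) != length(triggers) - 1L) {
    stop_data("need one validity flag per trigger-to-trigger interval")
  }
  idx <- findInterval(time, triggers)
  ok <- idx >= 1L & idx <= length(cycle_validity) & time <= triggers[length(triggers)]
  out <- rep(FALSE, length(time))
  out[ok] <- cycle_validity[idx[ok]]
  out
}

#' Assign amplitude gates
#'
#' Partitions every sample into one of `n_gates` equidistant amplitude bins
#' between the gating thresholds, or a rejection label: samples in invalid
#' cycles are `rejected_cycle`; remaining samples with amplitude outside the
#' closed threshold interval are `rejected_amplitude`. Bins are half-open
#' `[e_i, e_{i+1})` with the top bin closed at `thr_high`.
#'
#' @param r a [respiration_signal()] or numeric vector.
#' @param thresholds from [compute_thresholds()].
#' @param config a [gating_config()].
#' @param valid per-sample logical validity (from [cycle_validity_mask()]);
#'   default all valid.
#' @return an object of class `gating_result`: list with `thr_low`,
#'   `thr_high`, `gate_edges`, per-sample `labels` (factor with levels
#'   `gate_1 ... gate_n, rejected_amplitude, rejected_cycle`),
#'   `preserved_fraction` (percent per gate), `lost_fraction` (percent).
#' @export
assign_gates <- function(r, thresholds, config = gating_config(),
                         valid = NULL) {
  v <- as_values(r)
  n <- length(v)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n) stop_data("validity mask must match the signal")
  thr_low <- thresholds[["thr_low"]]; thr_high <- thresholds[["thr_high"]]
  if (thr_high <= thr_low) stop_degenerate("thresholds are degenerate")
  n_gates <- config$n_gates
  edges <- seq(thr_low, thr_high, length.out = n_gates + 1L)

  gate_levels <- paste0("gate_", seq_len(n_gates))
  labels <- factor(rep("rejected_cycle", n),
                   levels = c(gate_levels, "rejected_amplitude", "rejected_cycle"))
  in_amp <- valid & v >= thr_low & v <= thr_high
  labels[valid & !in_amp] <- "rejected_amplitude"
  bin <- pmin(floor((v[in_amp] - thr_low) / (thr_high - thr_low) * n_gates) + 1L,
              n_gates)  # top bin closed at thr_high
  labels[in_amp] <- gate_levels[bin]

  counts <- table(labels)
  preserved <- 100 * as.numeric(counts[gate_levels]) / n
  names(preserved) <- gate_levels
  lost <- 100 * sum(as.numeric(counts[c("rejected_amplitude", "rejected_cycle")])) / n
  structure(list(thr_low = thr_low, thr_high = thr_high, gate_edges = edges,
                 labels = labels, preserved_fraction = preserved,
                 lost_fraction = lost, n_samples = n),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("amplitude gating: thresholds [%.3f, %.3f], %d samples\n",
              x$thr_low, x$thr_high, x$n_samples))
  cat("  preserved per gate (%):",
      sprintf("%.2f", x$preserved_fraction), "\n")
  cat(sprintf("  lost data: %.2f%%\n", x$lost_fraction))
  invisible(x)
}

#' Convert gate labels to time windows
#'
#' Run-length encodes the per-sample labels into maximal contiguous
#' same-label time intervals (half-open, `t_end` = start of the sample after
#' the run), the form consumed by list-mode unlisting tools.
#'
#' @param result a [assign_gates()] result.
#' @param time sample times, s (uniform grid).
#' @return data.frame with columns `label`, `t_start`, `t_end`.
#' @export
export_gate_windows <- function(result, time) {
  stopifnot(inherits(result, "gating_result"))
  if (length(time) != length(result$labels)) {
    stop_data("time grid must match the labels")
  }
  r <- rle(as.character(result$labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- if (length(time) > 1) stats::median(diff(time)) else 0
  data.frame(label = r$values,
             t_start = time[starts],
             t_end = time[ends] + dt)
}

#' Serialise a gating result
#'
#' Writes the summary (thresholds, per-gate preserved fractions, lost
#' fraction) to JSON and the gate windows to CSV.
#'
#' @param result a [assign_gates()] result.
#' @param time sample times, s.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_gating <- function(result, time, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(thr_low = result$thr_low, thr_high = result$thr_high,
         gate_edges = result$gate_edges,
         preserved_fraction = as.list(result$preserved_fraction),
         lost_fraction = result$lost_fraction),
    file.path(path, "gating.json"), auto_unbox = TRUE, digits = NA)
  write.csv(export_gate_windows(result, time),
            file.path(path, "gate_windows.csv"), row.names = FALSE)
  invisible(path)
}
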