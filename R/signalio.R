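#' Raw recording of one IMU node
#'
#' Accelerometer and gyroscope streams with independent timestamp vectors
#' (the two sensors of a node sample at different rates).
#'
#' @param node_id 1 (sternum) or 2 (abdomen).
#' @param accel_time timestamps of the accelerometer stream, s.
#' @param accel N x 3 matrix of accelerations, m/s^2 (columns x, y, z).
#' @param gyro_time timestamps of the gyroscope stream, s.
#' @param gyro M x 3 matrix of angular rates, rad/s (columns x, y, z).
#' @return an object of class `node_recording`.
#' @export
node_recording <- function(node_id, accel_time, accel, gyro_time, gyro) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (ncol(accel) != 3 || ncol(gyro) != 3) {
    stop_data("accel and gyro must have three columns")
  }
  if (nrow(accel) != length(accel_time) || nrow(gyro) != length(gyro_time)) {
    stop_data("channel lengths must match their timestamp vectors")
  }
  if (is.unsorted(accel_time, strictly = TRUE) ||
      is.unsorted(gyro_time, strictly = TRUE)) {
    stop_data("timestamps must be strictly increasing")
  }
  structure(list(node_id = as.integer(node_id),
                 accel_time = as.numeric(accel_time), accel = unname(accel),
                 gyro_time = as.numeric(gyro_time), gyro = unname(gyro)),
            class = "node_recording")
}

#' @export
print.node_recording <- function(x, ...) {
  cat("IMU node", x$node_id, "recording:",
      length(x$accel_time), "accel samples,",
      length(x$gyro_time), "gyro samples,",
      sprintf("%.1f s\n", max(x$accel_time[length(x$accel_time)],
                              x$gyro_time[length(x$gyro_time)])))
  invisible(x)
}

#' A sampled 1-D respiration signal
#'
#' @param time sampling times, s (need not be uniform for the reference).
#' @param values signal samples.
#' @param unit `"a.u."` or `"cm"`.
#' @param kind one of `"shape"`, `"polmag"`, `"fused"`, `"reference"`.
#' @return an object of class `respiration_signal` (a data.frame with columns
#'   `time` and `value` and attributes `unit` and `kind`).
#' @export
respiration_signal <- function(time, values, unit = c("a.u.", "cm"),
                               kind = c("shape", "polmag", "fused", "reference")) {
  unit <- match.arg(unit); kind <- match.arg(kind)
  if (length(time) != length(values)) stop_data("time/value length mismatch")
  if (!all(is.finite(values))) stop_data("respiration signal must be finite")
  structure(data.frame(time = as.numeric(time), value = as.numeric(values)),
            unit = unit, kind = kind,
            class = c("respiration_signal", "data.frame"))
}

#' @export
print.respiration_signal <- function(x, ...) {
  cat(sprintf("respiration signal [%s], %d samples, %.1f s, unit %s\n",
              attr(x, "kind"), nrow(x), diff(range(x$time)), attr(x, "unit")))
  invisible(x)
}

#' Shift all timestamps of a signal or recording
#'
#' Applies the scanner-synchronisation clock offset: every timestamp is
#' shifted by `offset` seconds, values are untouched.
#'
#' @param x a `respiration_signal` or `node_recording`.
#' @param offset seconds to add to every timestamp.
#' @return `x` with shifted timestamps.
#' @export
apply_time_offset <- function(x, offset) {
  stopifnot(is.numeric(offset), length(offset) == 1)
  if (inherits(x, "respiration_signal")) {
    x$time <- x$time + offset
    if (!is.null(attr(x, "triggers"))) {
      attr(x, "triggers") <- attr(x, "triggers") + offset
    }
  } else if (inherits(x, "node_recording")) {
    x$accel_time <- x$accel_time + offset
    x$gyro_time <- x$gyro_time + offset
  } else {
    stop_data("apply_time_offset: unsupported object")
  }
  x
}

#' Resample both nodes onto the common analysis grid
#'
#' Linearly interpolates the sternum node's accelerometer x/y channels and the
#' abdomen node's accelerometer and gyroscope channels onto one uniform grid.
#' The grid covers only the common time support of all streams (no
#' extrapolation); its origin is the first common time rounded up to a
#' multiple of `1/fs`.
#'
#' @param rec1 sternum-node [node_recording()] (node 1).
#' @param rec2 abdomen-node [node_recording()] (node 2).
#' @param fs target sampling rate, Hz.
#' @return an object of class `resampled_record`: list with `time`,
#'   `node1_accel_xy` (N x 2), `node2_accel_xyz` (N x 3),
#'   `node2_gyro_xyz` (N x 3), `fs`.
#' @export
resample_to_grid <- function(rec1, rec2, fs = 100) {
  stopifnot(inherits(rec1, "node_recording"), inherits(rec2, "node_recording"))
  t_lo <- max(rec1$accel_time[1], rec2$accel_time[1], rec2$gyro_time[1])
  t_hi <- min(rec1$accel_time[length(rec1$accel_time)],
              rec2$accel_time[length(rec2$accel_time)],
              rec2$gyro_time[length(rec2$gyro_time)])
  if (t_hi - t_lo < 2 / fs) stop_data("streams have no usable common support")
  t0 <- ceiling(t_lo * fs) / fs
  grid <- t0 + seq(0, floor((t_hi - t0) * fs)) / fs
  interp <- function(tt, y) approx(tt, y, xout = grid)$y
  structure(list(
    time = grid,
    node1_accel_xy = cbind(interp(rec1$accel_time, rec1$accel[, 1]),
                           interp(rec1$accel_time, rec1$accel[, 2])),
    node2_accel_xyz = apply(rec2$accel, 2, interp, tt = rec2$accel_time),
    node2_gyro_xyz = apply(rec2$gyro, 2, interp, tt = rec2$gyro_time),
    fs = fs
  ), class = "resampled_record")
}

#' @export
print.resampled_record <- function(x, ...) {
  cat(sprintf("resampled record: %d samples at %g Hz (%.1f s)\n",
              length(x$time), x$fs, diff(range(x$time))))
  invisible(x)
}

#' Write a recording bundle to a directory
#'
#' Writes `node1.csv` and `node2.csv` (columns `t, ax, ay, az, gx, gy, gz`;
#' rows are the union of the two streams' timestamps, with empty cells where a
#' stream has no sample at that time), `reference.csv` (`t, value`),
#' `triggers.csv` (`t, valid_next_cycle`; the last trigger has no following
#' cycle) and, when given, a `config.yaml` echo.
#'
#' @param path directory to create/fill.
#' @param rec1,rec2 the two [node_recording()]s.
#' @param reference a reference [respiration_signal()] carrying `triggers` and
#'   `cycle_validity` attributes.
#' @param config optional named list echoed to `config.yaml`.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(path, rec1, rec2, reference, config = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_node <- function(rec, file) {
    df <- merge(
      data.frame(t = rec$accel_time, ax = rec$accel[, 1],
                 ay = rec$accel[, 2], az = rec$accel[, 3]),
      data.frame(t = rec$gyro_time, gx = rec$gyro[, 1],
                 gy = rec$gyro[, 2], gz = rec$gyro[, 3]),
      by = "t", all = TRUE)
    write.csv(df, file.path(path, file), row.names = FALSE, na = "")
  }
  write_node(rec1, "node1.csv")
  write_node(rec2, "node2.csv")
  write.csv(data.frame(t = reference$time, value = reference$value),
            file.path(path, "reference.csv"), row.names = FALSE)
  trig <- attr(reference, "triggers")
  valid <- attr(reference, "cycle_validity")
  write.csv(data.frame(t = trig, valid_next_cycle = c(valid, NA)),
            file.path(path, "triggers.csv"), row.names = FALSE, na = "")
  if (!is.null(config)) {
    yaml::write_yaml(config, file.path(path, "config.yaml"))
  }
  invisible(path)
}

#' Load a recording bundle
#'
#' Reads the directory layout written by [write_bundle()]. Rows with
#' unparseable or non-finite timestamps are dropped with a message stating
#' the count.
#'
#' @param path bundle directory.
#' @return list with `rec1`, `rec2` ([node_recording()]s), `reference`
#'   (a [respiration_signal()]), `triggers` (numeric) and `cycle_validity`
#'   (logical).
#' @export
load_bundle <- function(path) {
  need <- file.path(path, c("node1.csv", "node2.csv", "reference.csv",
                            "triggers.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop_io(paste("missing bundle file(s):", paste(basename(missing),
                                                   collapse = ", ")))
  }
  read_clean <- function(file, cols) {
    df <- read.csv(file, colClasses = "character")
    if (!all(cols %in% names(df))) {
      stop_data(paste0(basename(file), ": expected columns ",
                       paste(cols, collapse = ",")))
    }
    num <- as.data.frame(lapply(df[cols], function(x) suppressWarnings(as.numeric(x))))
    bad <- !is.finite(num$t)
    if (any(bad)) {
      message(sum(bad), " malformed row(s) rejected in ", basename(file))
      num <- num[!bad, , drop = FALSE]
    }
    num
  }
  read_node <- function(file, node_id) {
    df <- read_clean(file, c("t", "ax", "ay", "az", "gx", "gy", "gz"))
    a_ok <- stats::complete.cases(df[c("ax", "ay", "az")])
    g_ok <- stats::complete.cases(df[c("gx", "gy", "gz")])
    if (!any(a_ok) || !any(g_ok)) stop_data(paste(basename(file), "has an empty stream"))
    if (is.unsorted(df$t[a_ok], strictly = TRUE) ||
        is.unsorted(df$t[g_ok], strictly = TRUE)) {
      stop_data(paste(basename(file), "timestamps are not strictly increasing"))
    }
    node_recording(node_id,
                   accel_time = df$t[a_ok],
                   accel = as.matrix(df[a_ok, c("ax", "ay", "az")]),
                   gyro_time = df$t[g_ok],
                   gyro = as.matrix(df[g_ok, c("gx", "gy", "gz")]))
  }
  rec1 <- read_node(file.path(path, "node1.csv"), 1L)
  rec2 <- read_node(file.path(path, "node2.csv"), 2L)
  ref_df <- read_clean(file.path(path, "reference.csv"), c("t", "value"))
  ref_df <- ref_df[is.finite(ref_df$value), , drop = FALSE]
  if (nrow(ref_df) == 0) stop_data("reference.csv holds no usable samples")
  if (is.unsorted(ref_df$t, strictly = TRUE)) {
    stop_data("reference timestamps are not strictly increasing")
  }
  trig_df <- read.csv(file.path(path, "triggers.csv"))
  if (nrow(trig_df) == 0 || is.unsorted(trig_df$t, strictly = TRUE)) {
    stop_data("triggers.csv must hold strictly increasing timestamps")
  }
  validity <- as.logical(trig_df$valid_next_cycle[-nrow(trig_df)])
  reference <- respiration_signal(ref_df$t, ref_df$value,
                                  unit = "cm", kind = "reference")
  attr(reference, "triggers") <- trig_df$t
  attr(reference, "cycle_validity") <- validity
  list(rec1 = rec1, rec2 = rec2, reference = reference,
       triggers = trig_df$t, cycle_validity = validity)
}
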