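#' Causal moving average
#'
#' Trailing mean over the `min(w, i)` most recent samples, so the output has
#' the same length as the input and the filter is usable in real time. The
#' group delay for in-band respiration frequencies is approximately
#' `(w - 1) / (2 fs)` seconds.
#'
#' @param x numeric vector.
#' @param w window length in samples (`>= 1`).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' moving_average(c(1, 2, 3, 4), 2)  # 1.0 1.5 2.5 3.5
moving_average <- function(x, w) {
  if (w < 1) stop_config("moving average window must be >= 1")
  w <- as.integer(w)
  n <- length(x)
  cs <- cumsum(x)
  if (n <= w) return(cs / seq_len(n))
  head_part <- cs[seq_len(w)] / seq_len(w)
  tail_part <- (cs[(w + 1L):n] - cs[seq_len(n - w)]) / w
  c(head_part, tail_part)
}

#' Fit a 2-D PCA basis from a buffer of accelerometer samples
#'
#' Computes the column means and the eigenvectors of the sample covariance of
#' an N x 2 buffer. The principal directions are returned as rows in
#' descending order of explained variance; their sign is arbitrary (polarity
#' is resolved later against the position signal).
#'
#' @param buffer N x 2 numeric matrix (moving-averaged x/y channels).
#' @return an object of class `pca_basis`: list with `mean` (2-vector),
#'   `components` (2 x 2 orthonormal, rows = principal directions) and
#'   `variances` (non-increasing).
#' @export
fit_pca_basis <- function(buffer) {
  buffer <- as.matrix(buffer)
  if (ncol(buffer) != 2 || nrow(buffer) < 2) {
    stop_data("PCA buffer must be an N x 2 matrix with N >= 2")
  }
  mu <- colMeans(buffer)
  cv <- cov(buffer)
  if (!all(is.finite(cv)) || sum(diag(cv)) < 1e-24) {
    stop_degenerate("PCA buffer is rank-deficient (no variation)")
  }
  eg <- eigen(cv, symmetric = TRUE)
  structure(list(mean = mu, components = t(eg$vectors),
                 variances = pmax(eg$values, 0)),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("2-D PCA basis; explained variance:",
      sprintf("%.3g", x$variances), "\n")
  invisible(x)
}

#' Compute the shape signal s(t)
#'
#' Moving-averages the sternum node's accelerometer x and y channels, fits a
#' PCA basis from the first `n_circ` averaged samples, and projects the
#' mean-centred averaged channels onto the first principal direction for the
#' whole record. The basis (and the centring mean) is fitted once and then
#' frozen, so re-running on a longer record with the same opening segment
#' reproduces the same values on the overlap.
#'
#' @param rec a [resample_to_grid()] record.
#' @param params an [algorithm_params()].
#' @param refit_every optional integer: refit the basis from a sliding buffer
#'   every this many samples (streaming mode). `NULL` (default) keeps the
#'   single frozen fit.
#' @return a [respiration_signal()] of kind `"shape"` (arbitrary units), with
#'   the fitted basis attached as attribute `basis`.
#' @export
compute_shape_signal <- function(rec, params = algorithm_params(),
                                 refit_every = NULL) {
  stopifnot(inherits(rec, "resampled_record"))
  xy <- cbind(moving_average(rec$node1_accel_xy[, 1], params$w_avg_s),
              moving_average(rec$node1_accel_xy[, 2], params$w_avg_s))
  n <- nrow(xy)
  if (n < params$n_circ) {
    stop_data(sprintf("record too short for PCA buffer (%d < %d samples)",
                      n, params$n_circ))
  }
  basis <- fit_pca_basis(xy[seq_len(params$n_circ), ])
  s <- (xy[, 1] - basis$mean[1]) * basis$components[1, 1] +
       (xy[, 2] - basis$mean[2]) * basis$components[1, 2]
  if (!is.null(refit_every)) {
    refit_every <- as.integer(refit_every)
    starts <- seq(params$n_circ + refit_every, n, by = refit_every)
    for (i0 in starts) {
      buf <- xy[(i0 - params$n_circ + 1L):i0, ]
      b <- fit_pca_basis(buf)
      # keep the refit component's sign consistent with the frozen basis
      if (sum(b$components[1, ] * basis$components[1, ]) < 0) {
        b$components[1, ] <- -b$components[1, ]
      }
      idx <- i0:min(i0 + refit_every - 1L, n)
      s[idx] <- (xy[idx, 1] - b$mean[1]) * b$components[1, 1] +
                (xy[idx, 2] - b$mean[2]) * b$components[1, 2]
    }
  }
  out <- respiration_signal(rec$time, s, unit = "a.u.", kind = "shape")
  attr(out, "basis") <- basis
  out
}
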