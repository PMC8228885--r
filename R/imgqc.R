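#' Volume-of-interest uptake statistics
#'
#' @param myocardium_mean,myocardium_sd mean and standard deviation of uptake
#'   in the myocardium VOI, Bq/mL.
#' @param bloodpool_mean,bloodpool_sd mean and standard deviation of uptake
#'   in the blood-pool VOI, Bq/mL.
#' @return an object of class `voi_stats`.
#' @export
voi_stats <- function(myocardium_mean, myocardium_sd,
                      bloodpool_mean, bloodpool_sd) {
  if (myocardium_sd < 0 || bloodpool_sd < 0) {
    stop_data("standard deviations must be >= 0")
  }
  if (myocardium_mean <= 0 || bloodpool_mean <= 0) {
    stop_data("mean uptakes must be positive for ratio metrics")
  }
  structure(list(myocardium_mean = myocardium_mean,
                 myocardium_sd = myocardium_sd,
                 bloodpool_mean = bloodpool_mean,
                 bloodpool_sd = bloodpool_sd),
            class = "voi_stats")
}

#' Gated-image quality metrics from VOI statistics
#'
#' Computes the four standard VOI-based metrics:
#' contrast ratio `CR = myo_mean / blood_mean`,
#' signal-to-noise ratio `SNR = myo_mean / blood_sd`,
#' coefficient of variation `CV = myo_sd / myo_mean`, and
#' contrast-to-noise ratio `CNR = (myo_mean - blood_mean) / blood_sd`.
#'
#' @param v a [voi_stats()].
#' @return an object of class `image_quality_metrics`: list with `cr`,
#'   `snr`, `cv`, `cnr`.
#' @export
#' @examples
#' image_quality(voi_stats(100, 20, 80, 10))  # CR 1.25, SNR 10, CV 0.2, CNR 2
image_quality <- function(v) {
  stopifnot(inherits(v, "voi_stats"))
  if (v$bloodpool_sd == 0) stop_degenerate("blood-pool sd is zero")
  structure(list(cr = v$myocardium_mean / v$bloodpool_mean,
                 snr = v$myocardium_mean / v$bloodpool_sd,
                 cv = v$myocardium_sd / v$myocardium_mean,
                 cnr = (v$myocardium_mean - v$bloodpool_mean) / v$bloodpool_sd),
            class = "image_quality_metrics")
}

#' @export
print.image_quality_metrics <- function(x, ...) {
  cat(sprintf("CR %.4f  SNR %.4f  CV %.4f  CNR %.4f\n",
              x$cr, x$snr, x$cv, x$cnr))
  invisible(x)
}

#' Extract an intensity profile along a line through a volume
#'
#' Samples the volume by trilinear interpolation at uniform spacing (at most
#' half the smallest voxel dimension) along the segment between two physical
#' endpoints.
#'
#' @param volume 3-D numeric array.
#' @param voxel_size 3-vector of voxel edge lengths (physical units, e.g. mm).
#' @param from,to physical coordinates of the endpoints (the centre of voxel
#'   `[i, j, k]` is at `(i - 1) * voxel_size` etc., so the first voxel centre
#'   is the origin).
#' @return data.frame with columns `distance` (from `from`) and `value`.
#' @export
extract_profile <- function(volume, voxel_size, from, to) {
  stopifnot(length(dim(volume)) == 3, length(voxel_size) == 3,
            length(from) == 3, length(to) == 3)
  dims <- dim(volume)
  vox <- function(p) p / voxel_size  # physical -> 0-based voxel coordinates
  for (p in list(from, to)) {
    v <- vox(p)
    if (any(v < 0) || any(v > dims - 1)) stop_data("profile endpoint outside the volume")
  }
  len <- sqrt(sum((to - from)^2))
  spacing <- min(voxel_size) / 2
  n <- max(2L, ceiling(len / spacing) + 1L)
  tfrac <- seq(0, 1, length.out = n)
  pts <- cbind(from[1] + tfrac * (to[1] - from[1]),
               from[2] + tfrac * (to[2] - from[2]),
               from[3] + tfrac * (to[3] - from[3]))
  v <- sweep(pts, 2, voxel_size, "/")  # 0-based continuous voxel coords
  i0 <- pmin(pmax(floor(v[, 1]), 0), dims[1] - 2); fx <- v[, 1] - i0
  j0 <- pmin(pmax(floor(v[, 2]), 0), dims[2] - 2); fy <- v[, 2] - j0
  k0 <- pmin(pmax(floor(v[, 3]), 0), dims[3] - 2); fz <- v[, 3] - k0
  # degenerate axes (single slice): clamp to the only voxel, zero fraction
  fix <- function(i0, f, d) {
    if (d == 1) list(i0 = rep(0, length(i0)), f = rep(0, length(f)), i1 = rep(0, length(i0)))
    else list(i0 = i0, f = f, i1 = i0 + 1)
  }
  ax <- fix(i0, fx, dims[1]); ay <- fix(j0, fy, dims[2]); az <- fix(k0, fz, dims[3])
  at <- function(i, j, k) volume[cbind(i + 1, j + 1, k + 1)]
  val <-
    at(ax$i0, ay$i0, az$i0) * (1 - ax$f) * (1 - ay$f) * (1 - az$f) +
    at(ax$i1, ay$i0, az$i0) * ax$f       * (1 - ay$f) * (1 - az$f) +
    at(ax$i0, ay$i1, az$i0) * (1 - ax$f) * ay$f       * (1 - az$f) +
    at(ax$i0, ay$i0, az$i1) * (1 - ax$f) * (1 - ay$f) * az$f +
    at(ax$i1, ay$i1, az$i0) * ax$f       * ay$f       * (1 - az$f) +
    at(ax$i1, ay$i0, az$i1) * ax$f       * (1 - ay$f) * az$f +
    at(ax$i0, ay$i1, az$i1) * (1 - ax$f) * ay$f       * az$f +
    at(ax$i1, ay$i1, az$i1) * ax$f       * ay$f       * az$f
  data.frame(distance = tfrac * len, value = val)
}
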