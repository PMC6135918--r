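#' Construct an EEG recording object
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Hz, positive.
#' @param montage an `ms_montage`; the recording carries its scalp subset.
#' @param subject,group identifier strings.
#' @param mask logical per-sample usability flag (`TRUE` = usable); defaults
#'   to all usable.
#' @return list of class `ms_recording`.
#' @export
ms_recording <- function(data, sampling_rate, montage, subject = "S01",
                         group = NA_character_, mask = NULL) {
  stopifnot(is.matrix(data), sampling_rate > 0)
  n_scalp <- sum(montage$scalp)
  if (nrow(data) != n_scalp) {
    stop("channel count (", nrow(data), ") must equal the montage scalp subset size (",
         n_scalp, ")")
  }
  if (is.null(mask)) mask <- rep(TRUE, ncol(data))
  if (length(mask) != ncol(data)) stop("mask length must equal the sample count")
  structure(list(subject = subject, group = group, sampling_rate = sampling_rate,
                 data = data, mask = as.logical(mask), montage = montage),
            class = "ms_recording")
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf("<ms_recording> subject %s (%s): %d channels x %d samples @ %g Hz, %.1f%% usable\n",
              x$subject, x$group, nrow(x$data), ncol(x$data), x$sampling_rate,
              100 * mean(x$mask)))
  invisible(x)
}

# Zero-phase 4th-order Butterworth band-pass along columns of a
# samples x channels matrix.
bandpass_filter <- function(x, low, high, sampling_rate, order = 4L) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < sampling_rate/2")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  apply(x, 2, function(col) signal::filtfilt(bf, col))
}

#' Band-pass filter and re-reference a recording to the common average
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' per channel, then subtracts the instantaneous mean over scalp channels
#' from every sample. The artifact mask is carried through unchanged.
#'
#' @param recording an `ms_recording`.
#' @param low,high band edges in Hz (defaults 1 and 40).
#' @return an `ms_recording` with every sample average-referenced.
#' @export
bandpass_and_reref <- function(recording, low = 1, high = 40) {
  # remove per-channel means first: the high-pass kills DC anyway, and
  # centering avoids forward-backward filter edge transients from offsets
  centered <- recording$data - rowMeans(recording$data)
  filt <- t(bandpass_filter(t(centered), low, high, recording$sampling_rate))
  filt <- sweep(filt, 2, colMeans(filt))
  out <- recording
  out$data <- filt
  out
}

is_avg_referenced <- function(recording, tol = 1e-6) {
  scale <- max(mean(abs(recording$data)), .Machine$double.eps)
  max(abs(colMeans(recording$data))) <= tol * max(1, scale)
}

#' Global field power series of a recording
#'
#' GFP at each sample is the spatial standard deviation (divisor `N`) of the
#' average-referenced scalp map: `sqrt(mean(v^2))`.
#'
#' @param recording an average-referenced `ms_recording` (rejected
#'   otherwise).
#' @return list of class `ms_gfp`: `gfp` (per-sample, microvolts),
#'   `sampling_rate`, `mask`.
#' @export
compute_gfp <- function(recording) {
  if (!is_avg_referenced(recording)) {
    stop("recording must be average-referenced before computing GFP; ",
         "run bandpass_and_reref() first")
  }
  g <- sqrt(colMeans(recording$data^2))
  structure(list(gfp = g, sampling_rate = recording$sampling_rate,
                 mask = recording$mask), class = "ms_gfp")
}

#' Find local maxima of a GFP series within usable runs
#'
#' A peak is a sample `t` with `gfp(t-1) < gfp(t) > gfp(t+1)` whose both
#' immediate neighbors are usable; flat maxima contribute their first
#' sample; no peaks are reported at the boundaries of a usable run.
#'
#' @param gfp_series an `ms_gfp`, or a numeric GFP vector.
#' @param mask optional logical usability flag per sample (overrides the
#'   mask stored in `gfp_series`).
#' @return integer vector of peak sample indices (possibly empty).
#' @export
find_gfp_peaks <- function(gfp_series, mask = NULL) {
  g <- if (inherits(gfp_series, "ms_gfp")) gfp_series$gfp else as.numeric(gfp_series)
  if (is.null(mask)) {
    mask <- if (inherits(gfp_series, "ms_gfp")) gfp_series$mask else rep(TRUE, length(g))
  }
  if (length(mask) != length(g)) stop("gfp and mask must be aligned")
  n <- length(g)
  if (n < 3) return(integer(0))
  d <- sign(diff(g))
  # flat tops take their first sample: zero slopes inherit the next
  # nonzero slope to the right
  f <- rev(d); f[f == 0] <- NA
  ok <- !is.na(f); pos <- cumsum(ok); pos[pos == 0] <- NA
  f <- rev(f[ok][pos])
  idx <- 2:(n - 1)
  is_peak <- d[idx - 1] > 0 & !is.na(f[idx]) & f[idx] < 0
  usable <- mask[idx] & mask[idx - 1] & mask[idx + 1]
  idx[is_peak & usable]
}

# Split sample indices into maximal runs of usable samples.
usable_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  Map(function(s, e) s:e, starts[keep], ends[keep])
}

#' Extract normalized topographies at GFP peaks
#'
#' @param recording an average-referenced `ms_recording`.
#' @param peak_indices sample indices, e.g. from [find_gfp_peaks()].
#' @return matrix `n_peaks x n_channels` of unit-GFP, average-referenced
#'   maps.
#' @export
gfp_peak_maps <- function(recording, peak_indices) {
  maps <- t(recording$data[, peak_indices, drop = FALSE])
  normalize_map(maps)
}
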