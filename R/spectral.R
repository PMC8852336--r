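# From region time series to the band-power array: epoching, Welch PSD,
# band averaging, region aggregation.

#' Segment continuous region series into fixed-length epochs
#'
#' Cuts continuous signals into contiguous, non-overlapping epochs of
#' `epoch_length_s` seconds, preserving acquisition order and discarding
#' any trailing partial epoch. A 240-s session at 6-s epochs yields 40
#' epochs; a 420-s session yields 70.
#'
#' @param series numeric array `participants x regions x samples`, a
#'   matrix `participants x samples` (single region), or a vector (single
#'   participant and region).
#' @param fs_hz sampling rate in Hz.
#' @param epoch_length_s epoch duration in seconds (default 6).
#' @param region_labels optional region labels.
#' @return an [epoched_series()].
#' @export
epoch_series <- function(series, fs_hz, epoch_length_s = 6, region_labels = NULL) {
  if (is.vector(series) && is.numeric(series)) {
    series <- array(series, dim = c(1L, 1L, length(series)))
  } else if (is.matrix(series)) {
    series <- array(series, dim = c(nrow(series), 1L, ncol(series)))
  }
  if (!is.array(series) || length(dim(series)) != 3L) {
    stop("`series` must be a vector, matrix, or 3-D array (participants x regions x samples)",
         call. = FALSE)
  }
  nsamp_epoch <- as.integer(round(fs_hz * epoch_length_s))
  n_total <- dim(series)[3]
  n_epochs <- n_total %/% nsamp_epoch
  if (n_epochs < 2L) {
    stop("series shorter than two epochs: no split-half comparison is possible",
         call. = FALSE)
  }
  d <- dim(series)
  kept <- series[, , seq_len(n_epochs * nsamp_epoch), drop = FALSE]
  vals <- array(aperm(array(kept, dim = c(d[1], d[2], nsamp_epoch, n_epochs)),
                      c(1, 2, 4, 3)),
                dim = c(d[1], d[2], n_epochs, nsamp_epoch))
  epoched_series(vals, fs_hz = fs_hz, epoch_length_s = epoch_length_s,
                 region_labels = region_labels)
}

# Periodic Hann taper.
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# Welch PSD of the columns of a samples x series matrix. Returns a
# (n_freqs x n_series) matrix of one-sided density estimates; freqs
# attribute gives bin centers 0 .. fs/2.
welch_matrix <- function(x, fs_hz, nwin, noverlap, window = hann_window(nwin),
                         demean = TRUE) {
  n <- nrow(x)
  step <- nwin - noverlap
  starts <- seq(1L, n - nwin + 1L, by = step)
  U <- sum(window^2)
  half <- nwin %/% 2L
  acc <- matrix(0, half + 1L, ncol(x))
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1L), , drop = FALSE]
    if (demean) seg <- sweep(seg, 2L, colMeans(seg))
    X <- stats::mvfft(seg * window)
    pw <- Mod(X[1:(half + 1L), , drop = FALSE])^2 / (fs_hz * U)
    # one-sided density: double all bins except DC and Nyquist
    pw[2:half, ] <- 2 * pw[2:half, , drop = FALSE]
    acc <- acc + pw
  }
  out <- acc / length(starts)
  attr(out, "freqs") <- (0:half) * fs_hz / nwin
  out
}

#' Welch power spectral density per epoch
#'
#' Estimates a one-sided PSD for every (participant, region, epoch) cell
#' by Welch's method: the epoch is split into `window_length_s`-second
#' windows with the given fractional overlap, each window is mean-removed,
#' Hann-tapered, and its periodogram computed; periodograms are averaged.
#' The density normalization is such that summing density times bin width
#' over all frequencies returns the signal variance (Parseval), so
#' unit-variance white noise integrates to ~1. Frequency resolution is
#' `1 / window_length_s` Hz.
#'
#' @param x an [epoched_series()].
#' @param window_length_s Welch window length in seconds (default 3);
#'   must not exceed the epoch length.
#' @param overlap fractional window overlap in `[0, 1)` (default 0.5).
#' @return an [epoched_psd()] with dimensions
#'   `regions x frequencies x participants x epochs`.
#' @export
welch_psd <- function(x, window_length_s = 3, overlap = 0.5) {
  if (!inherits(x, "epoched_series")) stop("`x` must be an epoched_series", call. = FALSE)
  if (window_length_s > x$epoch_length_s + 1e-9) {
    stop("Welch window longer than the epoch", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  d <- dim(x$values)  # participants, regions, epochs, samples
  nwin <- as.integer(round(window_length_s * x$fs_hz))
  noverlap <- as.integer(round(nwin * overlap))
  w <- hann_window(nwin)
  half <- nwin %/% 2L
  out <- array(0, dim = c(d[2], half + 1L, d[1], d[3]))
  freqs <- NULL
  # chunk the FFT work per participant to bound memory
  for (s in seq_len(d[1])) {
    # samples x (regions*epochs) matrix for this participant
    m <- matrix(aperm(x$values[s, , , , drop = FALSE], c(4, 2, 3, 1)),
                nrow = d[4], ncol = d[2] * d[3])
    p <- welch_matrix(m, x$fs_hz, nwin, noverlap, w)
    if (is.null(freqs)) freqs <- attr(p, "freqs")
    out[, , s, ] <- aperm(array(p, dim = c(half + 1L, d[2], d[3])), c(2, 1, 3))
  }
  epoched_psd(out, freqs_hz = freqs, region_labels = x$regions,
              epoch_length_s = x$epoch_length_s)
}

#' Average PSD bins into frequency bands
#'
#' Reduces an epoched PSD to per-band power by taking, for each band, the
#' arithmetic mean of the PSD bins whose center frequency falls in the
#' band. Band-edge inclusion follows the band set's `edge` attribute:
#' `"closed"` uses `[f_lo, f_hi]` (the canonical set), `"left"` uses
#' `[f_lo, f_hi)` except the final band, which is closed (the
#' constant-bandwidth set).
#'
#' @param psd an [epoched_psd()].
#' @param band_defs band definition data.frame (default [canonical_bands()]).
#' @return a [band_power_array()] `regions x bands x participants x epochs`.
#' @export
band_average <- function(psd, band_defs = canonical_bands()) {
  if (!inherits(psd, "epoched_psd")) stop("`psd` must be an epoched_psd", call. = FALSE)
  validate_band_defs(band_defs)
  edge <- attr(band_defs, "edge") %||% "closed"
  d <- dim(psd$values)
  nb <- nrow(band_defs)
  out <- array(0, dim = c(d[1], nb, d[3], d[4]))
  for (b in seq_len(nb)) {
    lo <- band_defs$f_lo[b]; hi <- band_defs$f_hi[b]
    inband <- if (edge == "left" && b < nb) {
      psd$freqs_hz >= lo & psd$freqs_hz < hi
    } else {
      psd$freqs_hz >= lo & psd$freqs_hz <= hi
    }
    if (!any(inband)) {
      stop(sprintf("band '%s' (%g-%g Hz) contains no PSD bins", band_defs$name[b], lo, hi),
           call. = FALSE)
    }
    sub <- psd$values[, inband, , , drop = FALSE]
    out[, b, , ] <- apply(sub, c(1, 3, 4), mean)
  }
  band_power_array(out, band_defs = band_defs, region_labels = psd$regions,
                   epoch_length_s = psd$epoch_length_s)
}

#' Collapse a band-power array to a single global region
#'
#' Arithmetic mean over the region axis; used before the sample-size
#' subsampling analysis so each participant contributes one whole-cortex
#' value per band and epoch.
#'
#' @param x a [band_power_array()].
#' @return a [band_power_array()] with one region labelled `"global"`.
#' @export
region_mean <- function(x) {
  if (!inherits(x, "band_power_array")) stop("`x` must be a band_power_array", call. = FALSE)
  d <- dim(x$values)
  m <- apply(x$values, c(2, 3, 4), mean)
  band_power_array(array(m, dim = c(1L, d[2], d[3], d[4])),
                   band_defs = x$band_defs, region_labels = "global",
                   epoch_length_s = x$epoch_length_s,
                   ground_truth = x$ground_truth)
}
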