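# Lightweight S3 containers for the pipeline's array data.

#' Band-power array container
#'
#' The pipeline's central data structure: per-epoch band-averaged power,
#' organised as a 4-D array `regions x bands x participants x epochs`.
#'
#' @param values 4-D numeric array, dimensions regions, bands,
#'   participants, epochs (in that order).
#' @param band_defs band definition data.frame (see [canonical_bands()]),
#'   or `NULL` for unnamed bands.
#' @param region_labels character vector of region labels, length
#'   `dim(values)[1]`; defaults to the Desikan-Killiany set when the array
#'   has 68 regions, else `region_1 ...`.
#' @param epoch_length_s epoch duration in seconds (default 6).
#' @param ground_truth optional list recording generative parameters
#'   (attached by the synthetic generator).
#' @return an object of class `band_power_array`.
#' @export
band_power_array <- function(values, band_defs = NULL, region_labels = NULL,
                             epoch_length_s = 6, ground_truth = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L) {
    stop("`values` must be a 4-D array (regions x bands x participants x epochs)",
         call. = FALSE)
  }
  d <- dim(values)
  if (is.null(region_labels)) {
    region_labels <- if (d[1] == 68L) dk68_labels() else sprintf("region_%d", seq_len(d[1]))
  }
  if (length(region_labels) != d[1]) stop("region_labels length must match region dim", call. = FALSE)
  band_names <- if (!is.null(band_defs)) band_defs$name else sprintf("band_%d", seq_len(d[2]))
  if (length(band_names) != d[2]) stop("band definitions must match band dim", call. = FALSE)
  structure(
    list(values = values, band_defs = band_defs, bands = band_names,
         regions = region_labels, epoch_length_s = epoch_length_s,
         ground_truth = ground_truth),
    class = "band_power_array"
  )
}

#' @export
print.band_power_array <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<band_power_array> %d regions x %d bands x %d participants x %d epochs (%g s each)\n",
              d[1], d[2], d[3], d[4], x$epoch_length_s))
  cat("bands:", paste(x$bands, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.band_power_array <- function(x) dim(x$values)

#' Epoched region time-series container
#'
#' Fixed-length, contiguous, non-overlapping epochs of region-level
#' signal, organised as `participants x regions x epochs x samples`.
#'
#' @param values 4-D numeric array (participants, regions, epochs, samples).
#' @param fs_hz sampling rate in Hz.
#' @param epoch_length_s epoch duration in seconds; `samples` must equal
#'   `fs_hz * epoch_length_s` exactly.
#' @param region_labels optional region label vector.
#' @param ground_truth optional generative-parameter record.
#' @return an object of class `epoched_series`.
#' @export
epoched_series <- function(values, fs_hz, epoch_length_s,
                           region_labels = NULL, ground_truth = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L) {
    stop("`values` must be a 4-D array (participants x regions x epochs x samples)",
         call. = FALSE)
  }
  d <- dim(values)
  if (abs(d[4] - fs_hz * epoch_length_s) > 1e-9) {
    stop("samples per epoch must equal fs_hz * epoch_length_s exactly", call. = FALSE)
  }
  if (is.null(region_labels)) region_labels <- sprintf("region_%d", seq_len(d[2]))
  structure(
    list(values = values, fs_hz = fs_hz, epoch_length_s = epoch_length_s,
         regions = region_labels, ground_truth = ground_truth),
    class = "epoched_series"
  )
}

#' @export
print.epoched_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<epoched_series> %d participants x %d regions x %d epochs x %d samples @ %g Hz\n",
              d[1], d[2], d[3], d[4], x$fs_hz))
  invisible(x)
}

#' Epoched PSD container
#'
#' Welch power spectral density per epoch, organised as
#' `regions x frequencies x participants x epochs`, with the frequency-bin
#' vector attached.
#'
#' @param values 4-D numeric non-negative array.
#' @param freqs_hz frequency-bin centers (Hz), equally spaced.
#' @param region_labels optional region labels.
#' @param epoch_length_s epoch duration in seconds.
#' @return an object of class `epoched_psd`.
#' @export
epoched_psd <- function(values, freqs_hz, region_labels = NULL, epoch_length_s = 6) {
  if (!is.array(values) || length(dim(values)) != 4L) {
    stop("`values` must be a 4-D array (regions x freqs x participants x epochs)",
         call. = FALSE)
  }
  if (dim(values)[2] != length(freqs_hz)) stop("freqs_hz must match frequency dim", call. = FALSE)
  if (any(values < 0)) stop("PSD values must be non-negative", call. = FALSE)
  d <- dim(values)
  if (is.null(region_labels)) region_labels <- sprintf("region_%d", seq_len(d[1]))
  structure(
    list(values = values, freqs_hz = freqs_hz, regions = region_labels,
         epoch_length_s = epoch_length_s),
    class = "epoched_psd"
  )
}

#' @export
print.epoched_psd <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<epoched_psd> %d regions x %d freqs (%.3g-%.3g Hz) x %d participants x %d epochs\n",
              d[1], d[2], min(x$freqs_hz), max(x$freqs_hz), d[3], d[4]))
  invisible(x)
}
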