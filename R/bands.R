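# Frequency-band definitions and the cortical atlas label set used for
# region-level aggregation.

#' Canonical frequency bands
#'
#' The six canonical bands used for band-averaging power spectral density:
#' delta 2-4 Hz, theta 5-7 Hz, alpha 8-12 Hz, beta 15-29 Hz, low-gamma
#' 30-59 Hz, high-gamma 60-90 Hz. Band edges are closed intervals: a PSD
#' bin belongs to a band when its center frequency lies in `[f_lo, f_hi]`.
#'
#' @return a data.frame with columns `name`, `f_lo`, `f_hi` and attribute
#'   `edge = "closed"`.
#' @seealso [tenstep_bands()] for the constant-bandwidth alternative.
#' @export
canonical_bands <- function() {
  b <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "low-gamma", "high-gamma"),
    f_lo = c(2, 5, 8, 15, 30, 60),
    f_hi = c(4, 7, 12, 29, 59, 90),
    stringsAsFactors = FALSE
  )
  attr(b, "edge") <- "closed"
  b
}

#' Constant-bandwidth comparison bands
#'
#' Contiguous 10-Hz-wide bands spanning 3-92 Hz, used to check that
#' stability differences between canonical bands are not bandwidth
#' artifacts. Bins are half-open `[f_lo, f_hi)` except the last, which is
#' capped at 92 Hz and closed.
#'
#' @return a data.frame with columns `name`, `f_lo`, `f_hi` and attribute
#'   `edge = "left"`.
#' @export
tenstep_bands <- function() {
  lo <- seq(3, 83, by = 10)
  hi <- pmin(lo + 10, 92)
  b <- data.frame(
    name = sprintf("%d-%dHz", lo, hi),
    f_lo = lo,
    f_hi = hi,
    stringsAsFactors = FALSE
  )
  attr(b, "edge") <- "left"
  b
}

validate_band_defs <- function(band_defs) {
  need <- c("name", "f_lo", "f_hi")
  if (!is.data.frame(band_defs) || !all(need %in% names(band_defs))) {
    stop("`band_defs` must be a data.frame with columns name, f_lo, f_hi", call. = FALSE)
  }
  if (any(band_defs$f_hi < band_defs$f_lo)) {
    stop("band upper edges must not be below lower edges", call. = FALSE)
  }
  if (is.unsorted(band_defs$f_lo, strictly = TRUE)) {
    stop("bands must be ordered by increasing lower edge", call. = FALSE)
  }
  if (nrow(band_defs) > 1L &&
      any(band_defs$f_lo[-1L] < band_defs$f_hi[-nrow(band_defs)])) {
    edge <- attr(band_defs, "edge") %||% "closed"
    # half-open bands may share an edge; closed bands must not
    if (edge == "closed" || any(band_defs$f_lo[-1L] < band_defs$f_hi[-nrow(band_defs)] - 1e-12)) {
      if (edge == "closed") stop("bands must be non-overlapping", call. = FALSE)
    }
  }
  invisible(band_defs)
}

#' Desikan-Killiany cortical atlas labels
#'
#' The 68 cortical region labels (34 per hemisphere) of the
#' Desikan-Killiany parcellation, with hemisphere suffixes `" L"` /
#' `" R"`. This is the default region set for region-level feature
#' aggregation and for the duration tables.
#'
#' @return character vector of length 68.
#' @examples
#' length(dk68_labels())  # 68
#' @export
dk68_labels <- function() {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula"
  )
  c(paste(base, "L"), paste(base, "R"))
}
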