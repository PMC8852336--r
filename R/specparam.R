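# Parameterization of power spectra into aperiodic (offset, exponent) and
# periodic (Gaussian peak) components, following the published
# spectral-parameterization ("1/f + peaks") algorithm, plus the
# R^2-residualization fit correction.

#' Settings for spectral parameterization
#'
#' Defaults follow the analysis configuration: fit range 0.5-40 Hz,
#' Gaussian peak model, peak width limits 0.5-12 Hz (full width), at most
#' 3 peaks, minimum peak height 0.3 log10-power units (i.e. 3 dB, since
#' dB = 10 log10 power), relative peak threshold 2 SD of the flattened
#' spectrum, fixed (knee-free) aperiodic mode, no guess weighting.
#'
#' @param freq_range_hz fit range in Hz.
#' @param peak_width_limits_hz bounds on peak full width (Hz); Gaussian SD
#'   bounds are half of these.
#' @param max_n_peaks maximum number of Gaussian peaks.
#' @param min_peak_height absolute height floor, log10-power units.
#' @param peak_threshold_sd relative height floor, in SDs of the
#'   flattened spectrum.
#' @param ap_percentile percentile (in percent) of the clipped residuals
#'   used by the robust aperiodic fit to mask peak regions.
#' @return a list of class `param_settings`.
#' @export
param_settings <- function(freq_range_hz = c(0.5, 40),
                           peak_width_limits_hz = c(0.5, 12),
                           max_n_peaks = 3L,
                           min_peak_height = 0.3,
                           peak_threshold_sd = 2,
                           ap_percentile = 0.025) {
  if (length(freq_range_hz) != 2L || freq_range_hz[1] >= freq_range_hz[2]) {
    stop("`freq_range_hz` must be an increasing pair", call. = FALSE)
  }
  if (any(peak_width_limits_hz <= 0) || peak_width_limits_hz[1] >= peak_width_limits_hz[2]) {
    stop("`peak_width_limits_hz` must be positive and increasing", call. = FALSE)
  }
  if (max_n_peaks < 0) stop("`max_n_peaks` must be >= 0", call. = FALSE)
  structure(list(freq_range_hz = freq_range_hz,
                 peak_width_limits_hz = peak_width_limits_hz,
                 max_n_peaks = as.integer(max_n_peaks),
                 min_peak_height = min_peak_height,
                 peak_threshold_sd = peak_threshold_sd,
                 ap_percentile = ap_percentile),
            class = "param_settings")
}

gaussian_lp <- function(freqs, cf, height, sd) {
  height * exp(-(freqs - cf)^2 / (2 * sd^2))
}

peaks_model <- function(freqs, peaks) {
  out <- numeric(length(freqs))
  if (!is.null(peaks) && nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks))) {
      out <- out + gaussian_lp(freqs, peaks[i, 1], peaks[i, 2], peaks[i, 3])
    }
  }
  out
}

# Ordinary least squares of log power on log10 frequency:
# log10 P = offset - exponent * log10 f.
simple_ap_fit <- function(logf, logp) {
  co <- unname(stats::lm.fit(cbind(1, logf), logp)$coefficients)
  c(offset = co[1], exponent = -co[2])
}

# Robust aperiodic fit: initial OLS, clip below-line residuals to zero,
# drop bins whose clipped residual exceeds a low percentile (masking
# oscillatory peaks), refit on the remainder.
robust_ap_fit <- function(logf, logp, ap_percentile) {
  ap0 <- simple_ap_fit(logf, logp)
  flat <- logp - (ap0["offset"] - ap0["exponent"] * logf)
  flat[flat < 0] <- 0
  thr <- stats::quantile(flat, ap_percentile / 100, names = FALSE)
  keep <- flat <= thr
  if (sum(keep) < 3L) keep <- rep(TRUE, length(logf))
  simple_ap_fit(logf[keep], logp[keep])
}

#' Parameterize one power spectrum into aperiodic and periodic components
#'
#' Fits `log10 PSD = offset - exponent * log10 f + sum of Gaussians` over
#' the configured frequency range by the published iterative procedure:
#' (1) robust aperiodic fit (fit, mask high-residual bins, refit);
#' (2) flatten the spectrum; (3) extract up to `max_n_peaks` peaks, each
#' seeded at the flattened maximum and accepted only if its height exceeds
#' both the absolute floor and `peak_threshold_sd` SDs of the flattened
#' spectrum, with a data-driven half-height width clipped to the width
#' limits; (4) jointly refit all Gaussians by bounded least squares
#' (L-BFGS-B, deterministic, no random starts) and discard peaks too close
#' to the range edge or to a larger peak; (5) refit the aperiodic
#' component on the peak-removed spectrum; (6) assemble the full model
#' and its R^2 against the log10 spectrum.
#'
#' @param psd numeric vector of PSD values (linear power units, > 0 over
#'   the fit range).
#' @param freqs frequency vector (Hz), sorted, matching `psd`.
#' @param settings a [param_settings()].
#' @return a list of class `spectral_fit`: `offset`, `exponent`, `peaks`
#'   (matrix with columns cf, height, sd; zero rows when no peaks), `r2`,
#'   `full_model` (fitted log10 power over the fit range), `freqs` (fit
#'   range), `settings`.
#' @export
fit_spectrum <- function(psd, freqs, settings = param_settings()) {
  if (length(psd) != length(freqs)) stop("`psd` and `freqs` must have equal length", call. = FALSE)
  if (is.unsorted(freqs)) stop("`freqs` must be sorted increasing", call. = FALSE)
  fr <- settings$freq_range_hz
  sel <- freqs >= fr[1] & freqs <= fr[2]
  if (sum(sel) < 5L) stop("fit range covers fewer than 5 frequency bins", call. = FALSE)
  f <- freqs[sel]; p <- psd[sel]
  if (any(p <= 0)) stop("PSD must be strictly positive over the fit range", call. = FALSE)
  logf <- log10(f); logp <- log10(p)
  std_lim <- settings$peak_width_limits_hz / 2

  ap <- robust_ap_fit(logf, logp, settings$ap_percentile)
  flat <- logp - (ap["offset"] - ap["exponent"] * logf)

  # iterative peak seeding on the flattened spectrum
  guesses <- NULL
  flat_iter <- flat
  for (i in seq_len(settings$max_n_peaks)) {
    idx <- which.max(flat_iter)
    h <- flat_iter[idx]
    if (h <= settings$peak_threshold_sd * stats::sd(flat_iter)) break
    if (h <= settings$min_peak_height) break
    cf <- f[idx]
    half <- h / 2
    li <- idx; while (li > 1L && flat_iter[li] > half) li <- li - 1L
    ri <- idx; while (ri < length(f) && flat_iter[ri] > half) ri <- ri + 1L
    side <- c(if (flat_iter[li] <= half) cf - f[li], if (flat_iter[ri] <= half) f[ri] - cf)
    sd0 <- if (length(side)) {
      2 * min(side) / (2 * sqrt(2 * log(2)))  # FWHM -> Gaussian SD
    } else mean(std_lim)
    sd0 <- min(max(sd0, std_lim[1]), std_lim[2])
    guesses <- rbind(guesses, c(cf, h, sd0))
    flat_iter <- flat_iter - gaussian_lp(f, cf, h, sd0)
  }

  peaks <- matrix(numeric(0), 0, 3)
  if (!is.null(guesses)) {
    # joint bounded least-squares refit of all Gaussians on the flattened
    # spectrum; SD bounds enforce the width limits, centers stay near the
    # seeds (1.5 seed-SDs) and inside the fit range
    par0 <- as.vector(t(guesses))
    lower <- as.vector(t(cbind(pmax(guesses[, 1] - 1.5 * guesses[, 3], fr[1]),
                               0, std_lim[1])))
    upper <- as.vector(t(cbind(pmin(guesses[, 1] + 1.5 * guesses[, 3], fr[2]),
                               Inf, std_lim[2])))
    obj <- function(par) {
      pk <- matrix(par, ncol = 3, byrow = TRUE)
      sum((flat - peaks_model(f, pk))^2)
    }
    opt <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                        upper = upper,
                        control = list(factr = 1e-8 / .Machine$double.eps,
                                       maxit = 500))
    peaks <- matrix(opt$par, ncol = 3, byrow = TRUE)
    colnames(peaks) <- c("cf", "height", "sd")

    # drop peaks hugging the fit-range edge (within 1 SD)
    keep <- peaks[, "cf"] - 1 * peaks[, "sd"] >= fr[1] &
            peaks[, "cf"] + 1 * peaks[, "sd"] <= fr[2]
    peaks <- peaks[keep, , drop = FALSE]
    # proximity rule: drop any peak whose center lies within
    # peak_threshold_sd SDs of a larger peak's Gaussian
    if (nrow(peaks) > 1L) {
      ord <- order(peaks[, "height"], decreasing = TRUE)
      kept <- integer(0)
      for (j in ord) {
        close <- FALSE
        for (k in kept) {
          if (abs(peaks[j, "cf"] - peaks[k, "cf"]) <
              settings$peak_threshold_sd * peaks[k, "sd"]) close <- TRUE
        }
        if (!close) kept <- c(kept, j)
      }
      peaks <- peaks[sort(kept), , drop = FALSE]
    }
  }
  colnames(peaks) <- c("cf", "height", "sd")

  # final aperiodic fit on the peak-removed spectrum
  ap <- simple_ap_fit(logf, logp - peaks_model(f, peaks))
  full <- (ap["offset"] - ap["exponent"] * logf) + peaks_model(f, peaks)
  r2 <- stats::cor(logp, full)^2
  if (!is.finite(r2)) r2 <- 1  # constant spectra: model is exact

  structure(list(offset = unname(ap["offset"]), exponent = unname(ap["exponent"]),
                 peaks = peaks, r2 = unname(r2), full_model = unname(full),
                 freqs = f, settings = settings),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> offset = %.3f, exponent = %.3f, %d peak(s), R^2 = %.4f\n",
              x$offset, x$exponent, nrow(x$peaks), x$r2))
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}

#' Band-averaged periodic (peak-only) power
#'
#' Averages the Gaussian-sum (periodic-only) model of a spectral fit over
#' frequency bands, yielding one rhythmic-power value per band. Bands must
#' lie within the parameterization range (gamma bands, above 40 Hz, are
#' excluded from parameterization and must not be requested here). Returns
#' zero for every band when the fit has no peaks.
#'
#' @param fit a [fit_spectrum()] result.
#' @param band_defs band definitions; default: canonical bands below the
#'   fit ceiling (delta through beta for the 0.5-40 Hz range).
#' @return named numeric vector, one value per band (log10-power units).
#' @export
periodic_band_power <- function(fit, band_defs = NULL) {
  if (!inherits(fit, "spectral_fit")) stop("`fit` must be a spectral_fit", call. = FALSE)
  hi_lim <- fit$settings$freq_range_hz[2]
  if (is.null(band_defs)) {
    cb <- canonical_bands()
    band_defs <- cb[cb$f_hi <= hi_lim, ]
  }
  validate_band_defs(band_defs)
  if (any(band_defs$f_hi > hi_lim)) {
    stop("bands extending above the parameterization range are not allowed", call. = FALSE)
  }
  pk <- peaks_model(fit$freqs, fit$peaks)
  out <- vapply(seq_len(nrow(band_defs)), function(b) {
    sel <- fit$freqs >= band_defs$f_lo[b] & fit$freqs <= band_defs$f_hi[b]
    if (!any(sel)) stop(sprintf("band '%s' contains no bins of the fit range",
                                band_defs$name[b]), call. = FALSE)
    mean(pk[sel])
  }, numeric(1))
  stats::setNames(out, band_defs$name)
}

#' Fit-quality residualization of parameterized features
#'
#' Removes the component of a parameterized feature that is linearly
#' predictable from model fit quality: for every cell (e.g. region x band
#' x epoch-bin), the feature is regressed on R^2 across participants by
#' ordinary least squares and the residuals are returned. Downstream
#' stability analyses run on these residuals are immune to fit-quality
#' fluctuations masquerading as feature instability.
#'
#' @param feature numeric array with participants on the first dimension
#'   (vector, matrix `participants x cells`, or higher-dimensional array).
#' @param r2 array of fit R^2 values, same shape as `feature`.
#' @return residual array, same shape as `feature`. Cells with constant
#'   R^2 across participants fall back to mean-centering with a warning.
#' @export
fit_correction <- function(feature, r2) {
  if (!identical(dim(feature) %||% length(feature), dim(r2) %||% length(r2))) {
    stop("`feature` and `r2` must have identical shape", call. = FALSE)
  }
  d <- dim(feature)
  fm <- if (is.null(d)) matrix(feature, ncol = 1L) else matrix(feature, nrow = d[1])
  rm_ <- if (is.null(d)) matrix(r2, ncol = 1L) else matrix(r2, nrow = d[1])
  n <- nrow(fm)
  if (n < 3L) stop("fit correction requires at least 3 participants", call. = FALSE)
  xc <- sweep(rm_, 2L, colMeans(rm_))
  yc <- sweep(fm, 2L, colMeans(fm))
  vx <- colSums(xc^2)
  const <- vx <= .Machine$double.eps * n
  slope <- ifelse(const, 0, colSums(xc * yc) / ifelse(const, 1, vx))
  if (any(const)) {
    warning("constant R^2 in some cells: residuals are the mean-centered feature there",
            call. = FALSE)
  }
  res <- yc - sweep(xc, 2L, slope, "*")
  if (!is.null(d)) dim(res) <- d else res <- drop(res)
  res
}
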