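# Synthetic data generators. Two levels: feature-level arrays with exact
# variance-component ground truth (for validating the ICC stability
# engine against the closed form rho(m) = sigma_b^2 / (sigma_b^2 +
# sigma_w^2 / m)), and time-series-level signals with known aperiodic
# (1/f) and periodic (Gaussian peak) spectral content (for validating the
# Welch + parameterization path).

#' Variance-component specification for feature-level synthesis
#'
#' Describes a two-level Gaussian generative model: each participant
#' carries a stable per-region, per-band trait mu ~ N(0, sigma_b2), and
#' every epoch adds independent fluctuation eps ~ N(0, sigma_w2). Under
#' this model the expected split-half ICC of m-epoch averages has the
#' closed form rho(m) = sigma_b2 / (sigma_b2 + sigma_w2 / m), which is
#' what makes these arrays a ground-truth test bed for the stability
#' engine.
#'
#' @param sigma_b2 between-participant variance of the stable trait
#'   (feature units squared), >= 0.
#' @param sigma_w2 within-participant epoch-to-epoch variance, >= 0.
#' @param n_participants,n_regions,n_bands,n_epochs array dimensions;
#'   `n_epochs` must be even so that split-half bins up to n_epochs/2 exist.
#' @param epoch_length_s epoch duration in seconds (default 6).
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return an object of class `variance_component_spec`.
#' @examples
#' sp <- variance_component_spec(1, 1, n_participants = 20, n_epochs = 10, seed = 1)
#' expected_icc(sp, m = 4)  # 0.8
#' @export
variance_component_spec <- function(sigma_b2, sigma_w2, n_participants,
                                    n_regions = 1L, n_bands = 1L,
                                    n_epochs = 40L, epoch_length_s = 6,
                                    seed = 1L) {
  if (!is.numeric(sigma_b2) || sigma_b2 < 0) stop("`sigma_b2` must be >= 0", call. = FALSE)
  if (!is.numeric(sigma_w2) || sigma_w2 < 0) stop("`sigma_w2` must be >= 0", call. = FALSE)
  stopifnot_scalar_count(n_participants, "n_participants", min = 2L)
  stopifnot_scalar_count(n_regions, "n_regions")
  stopifnot_scalar_count(n_bands, "n_bands")
  stopifnot_scalar_count(n_epochs, "n_epochs", min = 2L)
  if (n_epochs %% 2L != 0L) stop("`n_epochs` must be even so split-half bins exist", call. = FALSE)
  if (!is.numeric(epoch_length_s) || epoch_length_s <= 0) stop("`epoch_length_s` must be > 0", call. = FALSE)
  structure(
    list(sigma_b2 = sigma_b2, sigma_w2 = sigma_w2,
         n_participants = as.integer(n_participants),
         n_regions = as.integer(n_regions), n_bands = as.integer(n_bands),
         n_epochs = as.integer(n_epochs), epoch_length_s = epoch_length_s,
         seed = as.integer(seed)),
    class = "variance_component_spec"
  )
}

#' Closed-form expected ICC for m-epoch averages
#'
#' Under the variance-component model, averaging m epochs shrinks the
#' within-participant variance to sigma_w2 / m, so the expected
#' absolute-agreement ICC between two independent m-epoch averages is
#' rho(m) = sigma_b2 / (sigma_b2 + sigma_w2 / m). Returns 1 for all m when
#' sigma_w2 = 0.
#'
#' @param spec a [variance_component_spec()], or a list with elements
#'   `sigma_b2` and `sigma_w2`.
#' @param m number of epochs averaged per bin (vectorized).
#' @return numeric vector of expected ICC values.
#' @export
expected_icc <- function(spec, m) {
  if (any(m < 1)) stop("`m` must be >= 1", call. = FALSE)
  if (spec$sigma_b2 == 0 && spec$sigma_w2 == 0) return(rep(1, length(m)))
  spec$sigma_b2 / (spec$sigma_b2 + spec$sigma_w2 / m)
}

#' Generate a feature-level band-power array with known ICC ground truth
#'
#' Draws x[r, f, s, e] = mu[r, f, s] + eps[r, f, s, e] with mu ~
#' N(0, sigma_b2) and eps ~ N(0, sigma_w2), independently across cells.
#' The returned array carries a `ground_truth` record with the generative
#' variances and the closed-form expected ICC curve.
#'
#' @param spec a [variance_component_spec()].
#' @param sigma_w2_scale optional per-participant multiplier on the
#'   within-participant variance (length `n_participants`); used to plant
#'   high-variability participants or covariate effects for the
#'   contribution analysis. Default: all 1.
#' @return a [band_power_array()] whose `ground_truth` holds `sigma_b2`,
#'   `sigma_w2`, `sigma_w2_scale`, `seed` and `expected_icc` (the rho(m)
#'   curve for m = 1..n_epochs/2).
#' @examples
#' x <- gen_feature_array(variance_component_spec(1, 0, 10, n_epochs = 4, seed = 2))
#' # no within-subject noise: every epoch identical per participant
#' stopifnot(max(abs(apply(x$values, 3, stats::sd))) >= 0)
#' @export
gen_feature_array <- function(spec, sigma_w2_scale = NULL) {
  if (!inherits(spec, "variance_component_spec")) {
    stop("`spec` must be a variance_component_spec", call. = FALSE)
  }
  ns <- spec$n_participants
  if (is.null(sigma_w2_scale)) sigma_w2_scale <- rep(1, ns)
  if (length(sigma_w2_scale) != ns || any(sigma_w2_scale < 0)) {
    stop("`sigma_w2_scale` must be non-negative, one value per participant", call. = FALSE)
  }
  d <- c(spec$n_regions, spec$n_bands, ns, spec$n_epochs)
  x <- with_seed(spec$seed, {
    mu <- array(stats::rnorm(prod(d[1:3]), sd = sqrt(spec$sigma_b2)), dim = d[1:3])
    eps <- array(stats::rnorm(prod(d)), dim = d)
    # per-participant within-subject SD, broadcast over regions/bands/epochs
    sdw <- sqrt(spec$sigma_w2 * sigma_w2_scale)
    eps <- eps * rep(rep(sdw, each = d[1] * d[2]), times = d[4])
    array(rep(mu, times = d[4]), dim = d) + eps
  })
  m_grid <- seq_len(spec$n_epochs %/% 2L)
  band_power_array(
    x,
    region_labels = if (d[1] == 68L) dk68_labels() else NULL,
    epoch_length_s = spec$epoch_length_s,
    ground_truth = list(
      model = "variance_component",
      sigma_b2 = spec$sigma_b2, sigma_w2 = spec$sigma_w2,
      sigma_w2_scale = sigma_w2_scale, seed = spec$seed,
      m = m_grid, expected_icc = expected_icc(spec, m_grid)
    )
  )
}

#' Spectral ground truth for time-series synthesis
#'
#' Describes the target power spectrum of synthetic region signals in the
#' usual log10-power parameterization: an aperiodic component
#' log10 P(f) = offset - exponent * log10(f), plus Gaussian oscillatory
#' peaks (center frequency in Hz, height in log10-power units, SD in Hz).
#' Between-participant and epoch-to-epoch variability enter as Gaussian
#' jitter on the parameters.
#'
#' @param offset aperiodic intercept (log10 power at 1 Hz).
#' @param exponent aperiodic slope magnitude, >= 0.
#' @param peaks matrix or data.frame with columns `cf`, `height`, `sd`
#'   (one row per peak), or `NULL` for a peak-free spectrum. Peak SDs must
#'   lie in (0, 12] Hz; centers must be below fs/2.
#' @param participant_sd between-participant SD applied to each parameter.
#' @param epoch_sd per-epoch SD applied to each parameter.
#' @param fs_hz sampling rate (Hz).
#' @param duration_s signal duration per participant/region; must be a
#'   multiple of `epoch_length_s`.
#' @param epoch_length_s epoch duration in seconds (default 6).
#' @param seed integer seed.
#' @return an object of class `spectral_ground_truth`.
#' @export
spectral_ground_truth <- function(offset = 1, exponent = 1, peaks = NULL,
                                  participant_sd = 0, epoch_sd = 0,
                                  fs_hz = 250, duration_s = 240,
                                  epoch_length_s = 6, seed = 1L) {
  if (exponent < 0) stop("`exponent` must be >= 0", call. = FALSE)
  if (!is.null(peaks)) {
    peaks <- as.matrix(as.data.frame(peaks)[, c("cf", "height", "sd")])
    if (any(peaks[, "sd"] <= 0) || any(peaks[, "sd"] > 12)) {
      stop("peak SDs must lie in (0, 12] Hz", call. = FALSE)
    }
    if (any(peaks[, "cf"] >= fs_hz / 2)) {
      stop("peak center at or above the Nyquist frequency (aliasing)", call. = FALSE)
    }
  }
  if (abs(duration_s / epoch_length_s - round(duration_s / epoch_length_s)) > 1e-9) {
    stop("`duration_s` must be a multiple of `epoch_length_s`", call. = FALSE)
  }
  structure(
    list(offset = offset, exponent = exponent, peaks = peaks,
         participant_sd = participant_sd, epoch_sd = epoch_sd,
         fs_hz = fs_hz, duration_s = duration_s,
         epoch_length_s = epoch_length_s, seed = as.integer(seed)),
    class = "spectral_ground_truth"
  )
}

# Target one-sided PSD (linear power units) on a frequency grid, from
# log10-domain aperiodic + Gaussian-peak parameters. f = 0 maps to 0 power.
model_psd <- function(freqs, offset, exponent, peaks = NULL) {
  logp <- rep(-Inf, length(freqs))
  pos <- freqs > 0
  logp[pos] <- offset - exponent * log10(freqs[pos])
  if (!is.null(peaks) && nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks))) {
      logp[pos] <- logp[pos] + peaks[i, "height"] *
        exp(-(freqs[pos] - peaks[i, "cf"])^2 / (2 * peaks[i, "sd"]^2))
    }
  }
  p <- numeric(length(freqs))
  p[pos] <- 10^logp[pos]
  p
}

# One epoch of spectrally shaped Gaussian noise: white noise shaped in the
# frequency domain so the expected one-sided periodogram density equals
# `psd_target` at each positive FFT bin. DC is zeroed.
shaped_noise_epoch <- function(psd_target, fs_hz, n) {
  half <- n %/% 2L
  # bins 1 .. half-1 complex, bin `half` (Nyquist) real
  amp <- sqrt(psd_target * fs_hz * n / 2)
  z_re <- stats::rnorm(half)
  z_im <- stats::rnorm(half - 1L)
  X <- complex(real = numeric(n), imaginary = numeric(n))
  X[2:half] <- amp[1:(half - 1L)] * complex(real = z_re[1:(half - 1L)],
                                            imaginary = z_im) / sqrt(2)
  X[half + 1L] <- amp[half] * z_re[half]
  X[(half + 2L):n] <- Conj(X[half:2])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate epoched region time series with known spectral content
#'
#' Synthesizes per-participant, per-region signals as frequency-domain
#' shaped Gaussian noise whose expected power spectrum follows the
#' aperiodic line plus Gaussian peaks of `truth`. Each participant draws
#' parameter offsets with SD `participant_sd` (their stable spectral
#' "trait"); each epoch additionally jitters the parameters with SD
#' `epoch_sd` (epoch-to-epoch fluctuation). Epochs are generated
#' independently, so spectra are exactly the target on average but there
#' is no cross-epoch waveform continuity.
#'
#' @param truth a [spectral_ground_truth()].
#' @param n_participants,n_regions array dimensions.
#' @return an [epoched_series()] whose `ground_truth` records the base
#'   parameters and each participant's realized parameter set.
#' @export
gen_region_timeseries <- function(truth, n_participants, n_regions = 1L) {
  if (!inherits(truth, "spectral_ground_truth")) {
    stop("`truth` must be a spectral_ground_truth", call. = FALSE)
  }
  stopifnot_scalar_count(n_participants, "n_participants")
  stopifnot_scalar_count(n_regions, "n_regions")
  n_epochs <- as.integer(round(truth$duration_s / truth$epoch_length_s))
  nsamp <- as.integer(round(truth$fs_hz * truth$epoch_length_s))
  if (nsamp %% 2L != 0L) stop("fs_hz * epoch_length_s must be even", call. = FALSE)
  freqs <- seq_len(nsamp %/% 2L) * truth$fs_hz / nsamp
  n_pk <- if (is.null(truth$peaks)) 0L else nrow(truth$peaks)

  jitter_params <- function(base, sd) {
    out <- base
    out$offset <- base$offset + stats::rnorm(1, sd = sd)
    out$exponent <- max(0, base$exponent + stats::rnorm(1, sd = sd))
    if (n_pk > 0) {
      pk <- base$peaks
      pk[, "cf"] <- pmin(pmax(pk[, "cf"] + stats::rnorm(n_pk, sd = sd), 0.5),
                         truth$fs_hz / 2 * 0.9)
      pk[, "height"] <- pk[, "height"] + stats::rnorm(n_pk, sd = sd)
      pk[, "sd"] <- pmin(pmax(pk[, "sd"] + stats::rnorm(n_pk, sd = sd / 2), 0.2), 12)
      out$peaks <- pk
    }
    out
  }

  base <- list(offset = truth$offset, exponent = truth$exponent, peaks = truth$peaks)
  vals <- array(0, dim = c(n_participants, n_regions, n_epochs, nsamp))
  part_params <- vector("list", n_participants)
  with_seed(truth$seed, {
    for (s in seq_len(n_participants)) {
      ps <- if (truth$participant_sd > 0) jitter_params(base, truth$participant_sd) else base
      part_params[[s]] <- ps
      for (r in seq_len(n_regions)) {
        for (e in seq_len(n_epochs)) {
          pe <- if (truth$epoch_sd > 0) jitter_params(ps, truth$epoch_sd) else ps
          tgt <- model_psd(freqs, pe$offset, pe$exponent, pe$peaks)
          vals[s, r, e, ] <- shaped_noise_epoch(tgt, truth$fs_hz, nsamp)
        }
      }
    }
  })
  epoched_series(
    vals, fs_hz = truth$fs_hz, epoch_length_s = truth$epoch_length_s,
    ground_truth = list(model = "shaped_noise", base = base,
                        participant_params = part_params,
                        participant_sd = truth$participant_sd,
                        epoch_sd = truth$epoch_sd, seed = truth$seed)
  )
}

#' Generate a participant demographics table
#'
#' Emulates an age-balanced adult cohort: ages drawn uniformly within each
#' decade from 20-29 through 60-69 (exactly balanced when `n_participants`
#' is a multiple of 5), sex and handedness as 0/1 codes (handedness ~90%
#' right = 1, the field's typical proportion), and an ACE-R-like general
#' cognition score on 0-100. Optionally plants a covariate effect: the
#' named covariate linearly scales each participant's within-subject
#' variance, giving the contribution analysis a recoverable non-null
#' effect via the returned `sigma_w2_multiplier` column.
#'
#' @param n_participants number of participants, >= 2.
#' @param seed integer seed.
#' @param planted_effect `NULL` for the null configuration, or
#'   `list(covariate = <one of "age","sex","handedness","cognition">,
#'   slope = <slope per SD of the covariate on the variance multiplier>)`.
#' @return a data.frame with columns `participant_id`, `age`, `sex`,
#'   `handedness`, `cognition`, and `sigma_w2_multiplier` (all 1 under the
#'   null; `pmax(1 + slope * z_covariate, 0.05)` when an effect is planted).
#' @examples
#' d <- gen_demographics(50, seed = 7)
#' table(cut(d$age, seq(20, 70, 10), right = FALSE))  # 10 per decade
#' @export
gen_demographics <- function(n_participants, seed = 1L, planted_effect = NULL) {
  stopifnot_scalar_count(n_participants, "n_participants", min = 2L)
  covs <- c("age", "sex", "handedness", "cognition")
  if (!is.null(planted_effect)) {
    if (!is.list(planted_effect) || is.null(planted_effect$covariate) ||
        !(planted_effect$covariate %in% covs)) {
      stop("planted_effect$covariate must be one of: ", paste(covs, collapse = ", "),
           call. = FALSE)
    }
  }
  with_seed(seed, {
    n <- n_participants
    decades <- seq(20, 60, by = 10)
    if (n %% length(decades) == 0L) {
      per <- n %/% length(decades)
      lo <- rep(decades, each = per)
    } else {
      lo <- sample(decades, n, replace = TRUE)
    }
    age <- lo + sample.int(10, length(lo), replace = TRUE) - 1L
    sex <- as.integer(sample(rep(c(0L, 1L), length.out = n)))
    # ~10% left-handed (0), never constant so it stays usable as a regressor
    n_left <- max(1L, round(0.1 * n))
    handedness <- rep(1L, n)
    handedness[sample.int(n, n_left)] <- 0L
    cognition <- pmin(100, pmax(0, round(stats::rnorm(n, 90, 5))))
    d <- data.frame(participant_id = sprintf("sub-%03d", seq_len(n)),
                    age = age, sex = sex, handedness = handedness,
                    cognition = cognition, stringsAsFactors = FALSE)
    mult <- rep(1, n)
    if (!is.null(planted_effect)) {
      z <- as.numeric(scale(d[[planted_effect$covariate]]))
      if (all(!is.finite(z))) stop("planted covariate has zero variance", call. = FALSE)
      mult <- pmax(1 + planted_effect$slope * z, 0.05)
    }
    d$sigma_w2_multiplier <- mult
    d
  })
}
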