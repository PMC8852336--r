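# Individual stability contribution analysis: leave-one-out time-by-ICC
# curves, trapezoidal AUC, delta-AUC influence scores, and per-covariate
# frequentist + Bayesian (JZS) tests.

#' Leave-one-out stability-contribution scores (delta AUC)
#'
#' For the full sample and every leave-one-out subset, under the SAME
#' epoch-permutation schedule, computes per band the across-region median
#' ICC at each bin size, takes the median across permutations (one
#' time-by-ICC curve per band and subset), and reduces each curve to its
#' trapezoidal area under the curve over duration in seconds. The
#' influence score is `delta_auc[i, band] = auc_full[band] - auc_loo[i,
#' band]`: the higher a participant's delta AUC, the more stable the
#' group model is when they are included.
#'
#' The leave-one-out ICCs are obtained by downdating the full-sample
#' sufficient statistics (participant sums), so all n + 1 analyses share
#' every permutation exactly.
#'
#' @param x a [band_power_array()] with at least 4 participants.
#' @param schedule a [permutation_schedule()] matching the array's epochs.
#' @return an object of class `contribution_scores`: `delta_auc`
#'   (participants x bands), `auc_full` (bands), `auc_loo`
#'   (participants x bands), `curve_full` (bands x durations),
#'   `durations_s`, `bands`.
#' @export
loo_stability_auc <- function(x, schedule) {
  bp <- as_band_power(x)
  d <- dim(bp$values)
  R <- d[1]; F_ <- d[2]; S <- d[3]; E <- d[4]
  if (!inherits(schedule, "perm_schedule")) stop("`schedule` must be a perm_schedule", call. = FALSE)
  if (schedule$n_epochs != E) stop("schedule epoch count does not match the array", call. = FALSE)
  if (S < 4L) stop("leave-one-out analysis requires at least 4 participants", call. = FALSE)
  M <- E %/% 2L
  RF <- R * F_
  P <- schedule$n_permutations
  X <- matrix(bp$values, nrow = RF * S, ncol = E)

  # per permutation: across-region median ICC per (band, m), full + LOO
  full_p <- array(NA_real_, dim = c(P, F_, M))
  loo_p <- array(NA_real_, dim = c(P, S, F_, M))
  med_regions <- function(v) {
    # v: RF x M -> F x M median over regions
    if (R == 1L) { dim(v) <- c(F_, M); return(v) }
    dim(v) <- c(R, F_, M)
    apply(v, c(2, 3), stats::median)
  }
  # expand an RF x M total to RF x S x M for vectorized LOO downdating
  expand_s <- function(tot) aperm(array(tot, dim = c(RF, M, S)), c(1, 3, 2))
  for (p in seq_len(P)) {
    ab <- split_half_means(X, schedule$orders[p, ], M)
    # per-participant contributions to the sufficient statistics
    a <- ab$A; dim(a) <- c(RF, S, M)
    b <- ab$B; dim(b) <- c(RF, S, M)
    aa <- a^2; bb <- b^2; abt <- a * b
    tot <- function(z) colSums(aperm(z, c(2, 1, 3)))  # RF x M
    Sa <- tot(a); Sb <- tot(b); Saa <- tot(aa); Sbb <- tot(bb); Sab <- tot(abt)
    rfull <- icc_from_sums(Sa, Sb, Saa, Sbb, Sab, S, ci = FALSE)
    full_p[p, , ] <- med_regions(rfull$icc)
    rloo <- icc_from_sums(expand_s(Sa) - a, expand_s(Sb) - b,
                          expand_s(Saa) - aa, expand_s(Sbb) - bb,
                          expand_s(Sab) - abt, S - 1L, ci = FALSE)
    v <- rloo$icc  # RF x S x M
    if (R == 1L) {
      loo_p[p, , , ] <- aperm(array(v, dim = c(F_, S, M)), c(2, 1, 3))
    } else {
      dim(v) <- c(R, F_, S, M)
      loo_p[p, , , ] <- aperm(apply(v, c(2, 3, 4), stats::median), c(2, 1, 3))
    }
  }

  durations <- seq_len(M) * bp$epoch_length_s
  curve_full <- apply(full_p, c(2, 3), stats::median)          # F x M
  curve_loo <- apply(loo_p, c(2, 3, 4), stats::median)         # S x F x M
  auc_full <- apply(curve_full, 1, function(y) trapz(durations, y))
  auc_loo <- apply(curve_loo, c(1, 2), function(y) trapz(durations, y))
  dimnames(auc_loo) <- list(NULL, bp$bands)
  names(auc_full) <- bp$bands
  delta <- sweep(-auc_loo, 2L, -auc_full)  # auc_full - auc_loo

  structure(list(delta_auc = delta, auc_full = auc_full, auc_loo = auc_loo,
                 curve_full = curve_full, durations_s = durations,
                 bands = bp$bands, n_participants = S),
            class = "contribution_scores")
}

#' @export
print.contribution_scores <- function(x, ...) {
  cat(sprintf("<contribution_scores> %d participants x %d bands (delta AUC, ICC*s)\n",
              x$n_participants, length(x$bands)))
  print(summary(x$delta_auc))
  invisible(x)
}

#' Jeffreys-Zellner-Siow Bayes factor for a single-covariate regression
#'
#' Computes BF01, the Bayes factor favoring the intercept-only model over
#' the one-covariate linear model, under the JZS prior: a Cauchy prior
#' with scale `rscale` on the standardized effect, implemented as a
#' zero-centered g-prior mixed over an inverse-gamma(1/2, n rscale^2 / 2)
#' distribution on g. The marginal likelihood ratio reduces to a
#' one-dimensional integral over g,
#' \deqn{BF_{10} = \int_0^\infty (1+g)^{(n-2)/2} (1+(1-R^2) g)^{-(n-1)/2}
#'   \sqrt{\frac{n r^2}{2\pi}}\, g^{-3/2} e^{-n r^2/(2g)} \, dg,}
#' evaluated by adaptive quadrature; BF01 = 1/BF10. The quadrature's
#' relative error estimate is reported alongside.
#'
#' @param response numeric response vector (e.g. a band's delta-AUC scores).
#' @param covariate numeric covariate vector (0/1 for categorical codes).
#' @param rscale Cauchy prior scale (default sqrt(2)/2, the conventional
#'   "medium" scale for regression slopes).
#' @return a list: `bf01`, `bf10`, `error` (relative numerical error),
#'   `r2`, `n`.
#' @examples
#' set.seed(1)
#' jzs_bf01(rnorm(50), rnorm(50))$bf01  # > 1: evidence for the null
#' @export
jzs_bf01 <- function(response, covariate, rscale = sqrt(2) / 2) {
  y <- as.numeric(response); x <- as.numeric(covariate)
  if (length(y) != length(x)) stop("`response` and `covariate` must have equal length", call. = FALSE)
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 4L) stop("JZS regression Bayes factor requires n >= 4", call. = FALSE)
  if (stats::var(x) <= .Machine$double.eps) stop("covariate is constant", call. = FALSE)
  r2 <- stats::cor(y, x)^2
  bf <- jzs_bf10_r2(r2, n, p = 1L, rscale = rscale)
  list(bf01 = 1 / bf$bf10, bf10 = bf$bf10, error = bf$error, r2 = r2, n = n)
}

# BF10 from R^2 by adaptive quadrature of the JZS integrand (log-space
# for numerical stability).
jzs_bf10_r2 <- function(r2, n, p = 1L, rscale = sqrt(2) / 2) {
  if (r2 < 0 || r2 >= 1) stop("R^2 must lie in [0, 1)", call. = FALSE)
  a <- n * rscale^2 / 2
  log_integrand <- function(g) {
    (n - p - 1) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r2) * g) +
      0.5 * log(a) - lgamma(0.5) - 1.5 * log(g) - a / g
  }
  # peak-rescaled integrand keeps the adaptive quadrature well-conditioned
  opt <- stats::optimize(log_integrand, c(1e-6, 1e6), maximum = TRUE)
  lmax <- opt$objective
  q <- stats::integrate(function(g) exp(log_integrand(g) - lmax), 0, Inf,
                        rel.tol = 1e-12, subdivisions = 2000L)
  if (q$message != "OK") stop("JZS quadrature did not converge: ", q$message, call. = FALSE)
  bf10 <- q$value * exp(lmax)
  list(bf10 = bf10, error = q$abs.error / q$value)
}

#' Per-covariate tests of stability-contribution scores
#'
#' For every band and covariate, regresses the participants' delta-AUC
#' scores on the single covariate by ordinary least squares (slope and
#' two-sided p-value, uncorrected for multiple comparisons) and computes
#' the JZS Bayes factor BF01 for the null of no effect. With the default
#' 6 bands and 4 covariates this is the 24-test design.
#'
#' @param scores a [loo_stability_auc()] result.
#' @param demographics a data.frame with one row per participant, in the
#'   same order as the array's participant axis (see
#'   [gen_demographics()]).
#' @param covariates covariate column names (default age, sex,
#'   handedness, cognition); all must be numeric-coded.
#' @param rscale Cauchy prior scale for the Bayes factors.
#' @return a data.frame of class `covariate_tests` with one row per
#'   (band, covariate): `slope`, `p_value`, `bf01`, `bf_error`.
#' @export
covariate_regression <- function(scores, demographics,
                                 covariates = c("age", "sex", "handedness", "cognition"),
                                 rscale = sqrt(2) / 2) {
  if (!inherits(scores, "contribution_scores")) {
    stop("`scores` must come from loo_stability_auc()", call. = FALSE)
  }
  if (nrow(demographics) != scores$n_participants) {
    stop("demographics rows must match the participant axis", call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(demographics))
  if (length(missing_cov)) {
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (f in seq_along(scores$bands)) {
    y <- scores$delta_auc[, f]
    for (cv in covariates) {
      x <- as.numeric(demographics[[cv]])
      if (stats::var(x) <= .Machine$double.eps) {
        stop(sprintf("covariate '%s' has zero variance", cv), call. = FALSE)
      }
      fit <- stats::lm(y ~ x)
      sm <- summary(fit)$coefficients
      bf <- jzs_bf01(y, x, rscale = rscale)
      rows[[length(rows) + 1L]] <- data.frame(
        band = scores$bands[f], covariate = cv,
        slope = sm[2, 1], p_value = sm[2, 4],
        bf01 = bf$bf01, bf_error = bf$error,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("covariate_tests", class(res))
  res
}
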