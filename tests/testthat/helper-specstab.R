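# Shared test helpers: independent oracles and fixture generators.

# Independent ICC(A,1) oracle: two-way ANOVA by direct summation, coded
# without reference to the package's sufficient-statistics path.
oracle_icc_a1 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  rowm <- rowMeans(mat); colm <- colMeans(mat)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Brute-force JZS Bayes factor oracle: trapezoidal integration of the
# g-mixture integrand on a dense log-spaced grid.
oracle_jzs_bf10 <- function(r2, n, rscale = sqrt(2) / 2, n_grid = 1e6) {
  a <- n * rscale^2 / 2
  g <- exp(seq(log(1e-8), log(1e8), length.out = n_grid))
  f <- exp((n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r2) * g) +
             0.5 * log(a) - lgamma(0.5) - 1.5 * log(g) - a / g)
  sum(diff(g) * (f[-1] + f[-length(f)]) / 2)
}

# Deterministic 20-spectrum battery with known aperiodic/periodic ground
# truth and mild log-domain noise. The same battery was fed to an
# independent scipy-based implementation of the parameterization
# algorithm; its fits are frozen in fixtures/specparam_battery_expected.csv.
make_specparam_battery <- function() {
  freqs <- seq(0.5, 40, by = 1 / 3)
  specstab:::with_seed(2024, {
    spectra <- list()
    truth <- list()
    for (i in 1:20) {
      offset <- stats::runif(1, -1, 2)
      exponent <- stats::runif(1, 0.5, 2)
      n_pk <- i %% 3  # cycles 1, 2, 0, 1, 2, 0, ...
      lp <- offset - exponent * log10(freqs)
      pks <- NULL
      if (n_pk >= 1) {
        cf1 <- stats::runif(1, 5, 15)
        h1 <- stats::runif(1, 0.4, 0.8)
        s1 <- stats::runif(1, 0.8, 2.0)
        pks <- rbind(pks, c(cf1, h1, s1))
      }
      if (n_pk == 2) {
        cf2 <- stats::runif(1, 20, 32)
        h2 <- stats::runif(1, 0.4, 0.7)
        s2 <- stats::runif(1, 1.0, 2.5)
        pks <- rbind(pks, c(cf2, h2, s2))
      }
      if (!is.null(pks)) {
        for (j in seq_len(nrow(pks))) {
          lp <- lp + pks[j, 2] * exp(-(freqs - pks[j, 1])^2 / (2 * pks[j, 3]^2))
        }
      }
      lp <- lp + stats::rnorm(length(freqs), sd = 0.02)
      spectra[[i]] <- 10^lp
      truth[[i]] <- list(offset = offset, exponent = exponent, peaks = pks,
                         n_peaks = n_pk)
    }
    list(freqs = freqs, spectra = spectra, truth = truth)
  })
}
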