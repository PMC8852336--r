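freqs_fit <- seq(0.5, 40, by = 1 / 3)

test_that("spectra in the model family are recovered exactly", {
  # pure aperiodic line
  fit <- fit_spectrum(10^(2 - 1.5 * log10(freqs_fit)), freqs_fit)
  expect_equal(fit$offset, 2, tolerance = 1e-6)
  expect_equal(fit$exponent, 1.5, tolerance = 1e-6)
  expect_identical(nrow(fit$peaks), 0L)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # line plus one alpha peak
  lp <- 1 - log10(freqs_fit) + 0.6 * exp(-(freqs_fit - 10)^2 / (2 * 1.2^2))
  fit1 <- fit_spectrum(10^lp, freqs_fit)
  expect_identical(nrow(fit1$peaks), 1L)
  expect_equal(unname(fit1$peaks[1, "cf"]), 10, tolerance = 0.5)
  expect_equal(unname(fit1$peaks[1, "height"]), 0.6, tolerance = 0.05)
  expect_equal(fit1$exponent, 1, tolerance = 0.02)

  # sub-threshold bump (height 0.1 < 0.3 floor) yields no peaks
  lp0 <- 1 - log10(freqs_fit) + 0.1 * exp(-(freqs_fit - 10)^2 / (2 * 1.2^2))
  expect_identical(nrow(fit_spectrum(10^lp0, freqs_fit)$peaks), 0L)
})

test_that("input validation rejects bad spectra", {
  expect_error(fit_spectrum(c(-1, rep(1, length(freqs_fit) - 1)), freqs_fit),
               "strictly positive")
  expect_error(fit_spectrum(rep(1, 10), seq(50, 59)), "fit range")
})

test_that("parameterization is scale-equivariant and model fit improves with peaks", {
  set.seed(31)
  for (i in 1:5) {
    off <- stats::runif(1, -1, 2); ex <- stats::runif(1, 0.5, 2)
    cf <- stats::runif(1, 6, 25)
    lp <- off - ex * log10(freqs_fit) +
      0.5 * exp(-(freqs_fit - cf)^2 / (2 * 1.5^2)) +
      stats::rnorm(length(freqs_fit), sd = 0.02)
    f1 <- fit_spectrum(10^lp, freqs_fit)
    f2 <- fit_spectrum(10^(lp + 1.7), freqs_fit)  # x 10^1.7 in power
    expect_equal(f2$offset - f1$offset, 1.7, tolerance = 1e-6)
    expect_equal(f2$exponent, f1$exponent, tolerance = 1e-6)
    expect_equal(f2$peaks[, "cf"], f1$peaks[, "cf"], tolerance = 1e-4)

    # full model beats the aperiodic-only description
    ap_only <- 10^(f1$offset - f1$exponent * log10(freqs_fit))
    r2_ap <- stats::cor(lp, log10(ap_only))^2
    expect_gte(f1$r2, r2_ap)
  }
})

test_that("fits agree with the independent scipy oracle on the frozen battery", {
  battery <- make_specparam_battery()
  expected <- utils::read.csv(test_path("fixtures", "specparam_battery_expected.csv"))
  for (i in 1:20) {
    fit <- fit_spectrum(battery$spectra[[i]], battery$freqs)
    expect_equal(fit$offset, expected$offset[i], tolerance = 0.05)
    expect_equal(fit$exponent, expected$exponent[i], tolerance = 0.05)
    expect_identical(nrow(fit$peaks), as.integer(expected$n_peaks[i]))
  }
})

test_that("periodic band power averages the Gaussian-only model", {
  lp <- 1 - log10(freqs_fit)
  no_pk <- fit_spectrum(10^lp, freqs_fit)
  expect_true(all(periodic_band_power(no_pk) == 0))

  # single alpha peak: alpha band dominates, distant bands near zero
  lp_a <- lp + 0.6 * exp(-(freqs_fit - 10)^2 / (2 * 1^2))
  pa <- periodic_band_power(fit_spectrum(10^lp_a, freqs_fit))
  expect_gt(pa[["alpha"]], 0.1)
  expect_lt(pa[["delta"]], 0.01)
  expect_lt(pa[["beta"]], 0.01)

  # two overlapping peaks: band mean equals direct evaluation of the sum
  fit2 <- fit_spectrum(10^(lp + 0.5 * exp(-(freqs_fit - 9)^2 / (2 * 2^2)) +
                             0.45 * exp(-(freqs_fit - 12)^2 / (2 * 2^2))), freqs_fit)
  pb <- periodic_band_power(fit2)
  direct <- vapply(seq_len(nrow(fit2$peaks)), function(j) {
    fit2$peaks[j, "height"] *
      exp(-(fit2$freqs - fit2$peaks[j, "cf"])^2 / (2 * fit2$peaks[j, "sd"]^2))
  }, numeric(length(fit2$freqs)))
  sel <- fit2$freqs >= 8 & fit2$freqs <= 12
  expect_equal(pb[["alpha"]], mean(rowSums(direct)[sel]), tolerance = 1e-10)

  # gamma bands lie above the parameterization range
  expect_error(periodic_band_power(fit2, canonical_bands()), "above the parameterization")
})

test_that("fit correction residualizes features on model fit quality", {
  set.seed(32)
  n <- 40
  r2 <- matrix(stats::runif(n * 3, 0.7, 1), n, 3)

  # feature = a + b * r2 exactly -> residuals 0
  feat_lin <- 2 + 5 * r2
  expect_equal(max(abs(fit_correction(feat_lin, r2))), 0, tolerance = 1e-10)

  # feature independent of r2 -> residuals ~ centered feature
  feat_ind <- matrix(stats::rnorm(n * 3), n, 3)
  res <- fit_correction(feat_ind, r2)
  cen <- sweep(feat_ind, 2, colMeans(feat_ind))
  expect_equal(res, cen, tolerance = 0.35)
  expect_equal(colMeans(res), c(0, 0, 0), tolerance = 1e-12)

  # constant r2 falls back to centering with a warning
  r2c <- r2; r2c[, 2] <- 0.9
  expect_warning(resc <- fit_correction(feat_ind, r2c), "constant R")
  expect_equal(resc[, 2], cen[, 2], tolerance = 1e-12)

  expect_error(fit_correction(feat_ind[1:2, ], r2[1:2, ]), "3 participants")
})

test_that("r2-coupled noise is suppressed by fit correction, improving stability", {
  # features contaminated by a shared fit-quality signal per epoch-half;
  # residualizing on r2 must not reduce split-half ICC
  set.seed(33)
  n <- 60
  trait <- stats::rnorm(n)
  icc_raw <- icc_cor <- numeric(4)
  for (h in 1:2) {
    r2h <- matrix(stats::runif(n, 0.6, 1), n, 1)
    feat <- trait + 3 * (r2h - 0.8) + stats::rnorm(n, sd = 0.3)
    assign(paste0("f", h), feat); assign(paste0("r", h), r2h)
  }
  raw <- icc_a1(cbind(f1, f2))$icc
  cor_ <- icc_a1(cbind(fit_correction(f1, r1), fit_correction(f2, r2)))$icc
  expect_gte(cor_, raw)
})
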