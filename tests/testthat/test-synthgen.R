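test_that("closed-form expected ICC follows the variance-component model", {
  noiseless <- variance_component_spec(2, 0, n_participants = 5, n_epochs = 4, seed = 1)
  expect_equal(expected_icc(noiseless, 1:2), c(1, 1))

  sp <- variance_component_spec(1, 1, n_participants = 5, n_epochs = 8, seed = 1)
  expect_equal(expected_icc(sp, 1), 0.5)
  expect_equal(expected_icc(sp, 4), 0.8)
  # non-decreasing in m whenever sigma_w2 > 0
  expect_true(all(diff(expected_icc(sp, 1:20)) > 0))
})

test_that("invalid variance-component specs are rejected", {
  expect_error(variance_component_spec(-1, 1, 10, n_epochs = 4), "sigma_b2")
  expect_error(variance_component_spec(1, -1, 10, n_epochs = 4), "sigma_w2")
  expect_error(variance_component_spec(1, 1, 10, n_epochs = 5), "even")
  expect_error(variance_component_spec(1, 1, 10, n_epochs = 4, epoch_length_s = 0),
               "epoch_length_s")
})

test_that("feature arrays are seed-deterministic and respect the variance model", {
  sp <- variance_component_spec(1.5, 0.5, n_participants = 400, n_regions = 2,
                                n_bands = 3, n_epochs = 10, seed = 42)
  x1 <- gen_feature_array(sp)
  x2 <- gen_feature_array(sp)
  expect_identical(x1$values, x2$values)
  expect_equal(dim(x1$values), c(2L, 3L, 400L, 10L))

  # variance accounting: var of participant means ~ sigma_b2 + sigma_w2/E
  pm <- apply(x1$values[1, 1, , ], 1, mean)
  expect_equal(stats::var(pm), 1.5 + 0.5 / 10, tolerance = 0.15)

  # no within-subject noise: epochs identical within participant
  x0 <- gen_feature_array(variance_component_spec(1, 0, 10, n_epochs = 4, seed = 7))
  expect_equal(max(abs(apply(x0$values[1, 1, , ], 1, stats::sd))), 0)
})

test_that("empirical split-half ICC of m-epoch averages matches rho(m)", {
  # sigma_b2 = 1, sigma_w2 = 4: rho(10) = 1 / (1 + 4/10) = 0.7143
  sp <- variance_component_spec(1, 4, n_participants = 200, n_epochs = 40, seed = 5)
  x <- gen_feature_array(sp)
  a <- apply(x$values[1, 1, , 1:10], 1, mean)
  b <- apply(x$values[1, 1, , 31:40], 1, mean)
  expect_equal(icc_a1(cbind(a, b))$icc, 1 / (1 + 4 / 10), tolerance = 0.12)
})

test_that("shaped-noise time series have the requested spectrum", {
  # flat-spectrum limit: exponent 0, no peaks -> white noise with PSD 10^offset
  tw <- spectral_ground_truth(offset = 0, exponent = 0, fs_hz = 250,
                              duration_s = 120, seed = 8)
  es <- gen_region_timeseries(tw, n_participants = 3)
  p <- welch_psd(es)
  mp <- apply(p$values[1, , , ], 1, mean)
  expect_equal(mean(mp[p$freqs_hz > 1]), 1, tolerance = 0.05)
  expect_lt(stats::sd(mp[p$freqs_hz > 1]) / mean(mp[p$freqs_hz > 1]), 0.1)

  # log-linear shift: +0.3 offset moves the fitted offset by ~0.3
  base <- spectral_ground_truth(offset = 1, exponent = 1, fs_hz = 250,
                                duration_s = 120, seed = 9)
  up <- spectral_ground_truth(offset = 1.3, exponent = 1, fs_hz = 250,
                              duration_s = 120, seed = 9)
  f1 <- fit_spectrum(apply(welch_psd(gen_region_timeseries(base, 2))$values[1, , , ], 1, mean),
                     welch_psd(gen_region_timeseries(base, 2))$freqs_hz)
  f2 <- fit_spectrum(apply(welch_psd(gen_region_timeseries(up, 2))$values[1, , , ], 1, mean),
                     welch_psd(gen_region_timeseries(up, 2))$freqs_hz)
  expect_equal(f2$offset - f1$offset, 0.3, tolerance = 0.05)

  # aliasing guard
  expect_error(spectral_ground_truth(peaks = data.frame(cf = 200, height = 1, sd = 2),
                                     fs_hz = 250), "Nyquist")
})

test_that("demographics cover the decades and plant effects correctly", {
  d <- gen_demographics(50, seed = 3)
  decades <- table(cut(d$age, seq(20, 70, 10), right = FALSE))
  expect_true(all(decades == 10))
  expect_true(all(d$sex %in% 0:1) && all(d$handedness %in% 0:1))
  expect_true(all(d$cognition >= 0 & d$cognition <= 100))
  expect_true(all(d$sigma_w2_multiplier == 1))

  dp <- gen_demographics(50, seed = 3, planted_effect = list(covariate = "age", slope = 0.5))
  expect_gt(stats::cor(dp$age, dp$sigma_w2_multiplier), 0.95)
  expect_true(all(dp$sigma_w2_multiplier > 0))

  expect_error(gen_demographics(20, seed = 1,
                                planted_effect = list(covariate = "iq", slope = 1)),
               "covariate")
})
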