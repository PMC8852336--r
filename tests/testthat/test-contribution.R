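test_that("trapezoidal AUC handles the constant-curve case", {
  # constant height 1 over 6..120 s: area (120 - 6) * 1 = 114
  expect_equal(trapz(seq(6, 120, by = 6), rep(1, 20)), 114)
  expect_error(trapz(c(1, 1, 2), c(0, 0, 0)), "strictly increasing")
})

test_that("leave-one-out delta AUC isolates a planted high-variance participant", {
  sp <- variance_component_spec(1, 1, n_participants = 20, n_regions = 3,
                                n_bands = 2, n_epochs = 20, seed = 41)
  scale <- rep(1, 20); scale[13] <- 10
  x <- gen_feature_array(sp, sigma_w2_scale = scale)
  sch <- permutation_schedule(20, 40, seed = 42)
  sc <- loo_stability_auc(x, sch)

  expect_equal(dim(sc$delta_auc), c(20L, 2L))
  expect_equal(sc$delta_auc, sweep(-sc$auc_loo, 2, -sc$auc_full), tolerance = 1e-12)
  expect_identical(which.min(sc$delta_auc[, 1]), 13L)
  expect_identical(which.min(sc$delta_auc[, 2]), 13L)

  # matched-schedule identity: rerunning without the planted participant
  # reproduces that participant's leave-out AUC exactly
  x2 <- x; x2$values <- x$values[, , -13, , drop = FALSE]
  sc2 <- loo_stability_auc(x2, sch)
  expect_equal(unname(sc2$auc_full), unname(sc$auc_loo[13, ]), tolerance = 1e-10)

  expect_error(loo_stability_auc(x, permutation_schedule(10, 5, seed = 1)),
               "epoch count")
})

test_that("delta AUC is scale-invariant and centers near zero for exchangeable samples", {
  sp <- variance_component_spec(1, 1, n_participants = 16, n_epochs = 12, seed = 43)
  x <- gen_feature_array(sp)
  sch <- permutation_schedule(12, 30, seed = 44)
  sc <- loo_stability_auc(x, sch)

  xs <- x; xs$values <- 7.3 * x$values
  expect_equal(loo_stability_auc(xs, sch)$delta_auc, sc$delta_auc, tolerance = 1e-9)

  # exchangeable participants: mean influence ~ 0 relative to the AUC scale
  expect_lt(abs(mean(sc$delta_auc[, 1])) / sc$auc_full[[1]], 0.05)
})

test_that("the JZS Bayes factor matches brute-force quadrature and behaves consistently", {
  # fixed toy data, zero true effect
  toy <- specstab:::with_seed(46, list(y = stats::rnorm(20), x = stats::rnorm(20)))
  bf <- jzs_bf01(toy$y, toy$x)
  oracle <- 1 / oracle_jzs_bf10(stats::cor(toy$y, toy$x)^2, 20)
  expect_equal(bf$bf01, oracle, tolerance = 5e-5)  # 4 significant digits
  expect_lt(bf$error, 1e-6)

  # no signal at n = 50: evidence favors the null
  flat <- specstab:::with_seed(47, list(y = stats::rnorm(50), x = stats::rnorm(50)))
  expect_gt(jzs_bf01(flat$y, flat$x)$bf01, 1)

  # bf01 -> 0 as the true slope grows at fixed n
  bfs <- vapply(c(0.5, 1, 2, 4), function(b) {
    d <- specstab:::with_seed(48, list(x = stats::rnorm(30)))
    jzs_bf01(b * d$x + specstab:::with_seed(49, stats::rnorm(30, sd = 0.5)), d$x)$bf01
  }, numeric(1))
  expect_true(all(diff(bfs) < 0))

  # continuity in the prior scale
  r_grid <- c(0.5, 0.6, 0.7, 0.8)
  bfr <- vapply(r_grid, function(r) jzs_bf01(toy$y, toy$x, rscale = r)$bf01, numeric(1))
  expect_true(all(abs(diff(bfr)) < 0.5))

  # large-n BIC approximation agrees within an order of magnitude on null data
  big <- specstab:::with_seed(50, list(y = stats::rnorm(200), x = stats::rnorm(200)))
  bf_big <- jzs_bf01(big$y, big$x)$bf01
  b0 <- stats::BIC(stats::lm(big$y ~ 1)); b1 <- stats::BIC(stats::lm(big$y ~ big$x))
  bic_bf01 <- exp((b1 - b0) / 2)
  expect_lt(abs(log10(bf_big / bic_bf01)), 1)

  expect_error(jzs_bf01(stats::rnorm(3), stats::rnorm(3)), "n >= 4")
  expect_error(jzs_bf01(stats::rnorm(10), rep(1, 10)), "constant")
})

test_that("covariate tests produce the full band-by-covariate design", {
  sp <- variance_component_spec(1, 1, n_participants = 24, n_bands = 6,
                                n_epochs = 12, seed = 51)
  x <- gen_feature_array(sp)
  sc <- loo_stability_auc(x, permutation_schedule(12, 25, seed = 52))
  demo <- gen_demographics(24, seed = 53)
  tests <- covariate_regression(sc, demo)

  expect_identical(nrow(tests), 24L)  # 6 bands x 4 covariates
  expect_true(all(tests$bf01 > 0))
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))

  # a covariate uncorrelated by construction has a near-zero standardized slope
  z <- as.numeric(scale(demo$age))
  fitz <- stats::lm(as.numeric(scale(sc$delta_auc[, 1])) ~ z)
  expect_lt(abs(stats::coef(fitz)[2]), 0.6)

  demo_const <- demo; demo_const$handedness <- 1L
  expect_error(covariate_regression(sc, demo_const), "handedness")
  expect_error(covariate_regression(sc, demo[1:10, ]), "participant")
})
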