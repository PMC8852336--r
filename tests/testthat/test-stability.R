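test_that("ICC(A,1) reproduces the two-way ANOVA definition", {
  # worked example: rows (1,2), (3,4), (5,6) -> MSR 8, MSC 1.5, MSE 0, ICC 8/9
  r <- icc_a1(cbind(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(r$icc, 8 / 9, tolerance = 1e-12)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)

  # identical columns with non-constant rows: perfect absolute agreement
  expect_equal(icc_a1(cbind(c(1, 2, 7), c(1, 2, 7)))$icc, 1)

  # a constant offset between columns is penalized (absolute agreement)
  expect_lt(icc_a1(cbind(c(1, 3, 5), c(1, 3, 5) + 2))$icc, 1)

  expect_error(icc_a1(cbind(1:2, 3:4)), "3 participants")
  expect_error(icc_a1(matrix(1:9, 3)), "2 measurement columns")
  expect_warning(r0 <- icc_a1(matrix(2, 4, 2)), "zero total variance")
  expect_equal(r0$icc, 1)
  expect_true(r0$degenerate)
})

test_that("ICC(A,1) matches an independently coded ANOVA oracle", {
  set.seed(99)
  for (i in 1:300) {
    m <- matrix(stats::rnorm(20), 10, 2)
    expect_equal(icc_a1(m)$icc, oracle_icc_a1(m), tolerance = 1e-10)
  }
  # structured cases: strong trait, pure noise, offset columns
  trait <- stats::rnorm(10)
  for (m in list(cbind(trait, trait + stats::rnorm(10, sd = 0.1)),
                 matrix(stats::rnorm(20), 10),
                 cbind(trait, trait + 5))) {
    expect_equal(icc_a1(m)$icc, oracle_icc_a1(m), tolerance = 1e-10)
  }
})

test_that("permutation schedules are reproducible permutations", {
  s1 <- permutation_schedule(12, 50, seed = 7)
  s2 <- permutation_schedule(12, 50, seed = 7)
  expect_identical(s1$orders, s2$orders)
  expect_true(all(apply(s1$orders, 1, function(o) identical(sort(o), 1:12))))
  expect_false(identical(s1$orders, permutation_schedule(12, 50, seed = 8)$orders))
})

test_that("stability curves recover the variance-component ground truth", {
  # noise-free traits: ICC exactly 1 at every bin size
  x0 <- gen_feature_array(variance_component_spec(1, 0, 20, n_epochs = 8, seed = 1))
  sch <- permutation_schedule(8, 20, seed = 2)
  sc0 <- stability_curves(x0, sch)
  expect_equal(max(abs(sc0$icc - 1)), 0, tolerance = 1e-12)

  # sigma_b2 = sigma_w2 = 1: median ICC at m ~ m / (m + 1)
  sp <- variance_component_spec(1, 1, n_participants = 150, n_epochs = 20, seed = 3)
  sc <- stability_curves(gen_feature_array(sp), permutation_schedule(20, 60, seed = 4))
  m <- c(1, 4, 10)
  expect_equal(unname(sc$icc[1, 1, m]), m / (m + 1), tolerance = 0.08)
  expect_identical(sc$durations_s, (1:10) * 6)

  # pre-permuting the epoch axis leaves the median curve statistically unchanged
  xp <- gen_feature_array(sp)
  set.seed(5)
  xp$values <- xp$values[, , , sample(20), drop = FALSE]
  scp <- stability_curves(xp, permutation_schedule(20, 60, seed = 4))
  expect_equal(scp$icc[1, 1, ], sc$icc[1, 1, ], tolerance = 0.05)
})

test_that("ICC scale and shift behaviour propagates through the curves", {
  sp <- variance_component_spec(1, 1, n_participants = 40, n_regions = 2,
                                n_epochs = 10, seed = 6)
  x <- gen_feature_array(sp)
  sch <- permutation_schedule(10, 25, seed = 7)
  base <- stability_curves(x, sch)

  # multiplying one region's values by a positive constant: its ICC unchanged
  xs <- x
  xs$values[2, , , ] <- 10 * xs$values[2, , , ]
  scaled <- stability_curves(xs, sch)
  expect_equal(scaled$icc[2, 1, ], base$icc[2, 1, ], tolerance = 1e-10)

  # adding a participant-specific constant adds trait variance: ICC increases
  xa <- x
  shift <- stats::rnorm(40, sd = 3)
  xa$values[1, , , ] <- sweep(xa$values[1, , , , drop = FALSE], 3, shift, "+")[1, , , ]
  shifted <- stability_curves(xa, sch)
  expect_true(all(shifted$icc[1, 1, ] > base$icc[1, 1, ]))
})

test_that("median curves are stable under re-seeding the schedule", {
  sp <- variance_component_spec(1, 1, n_participants = 120, n_epochs = 12, seed = 8)
  x <- gen_feature_array(sp)
  a <- stability_curves(x, permutation_schedule(12, 80, seed = 1))
  b <- stability_curves(x, permutation_schedule(12, 80, seed = 2))
  expect_equal(a$icc[1, 1, ], b$icc[1, 1, ], tolerance = 0.03)
})

make_fake_curve <- function(curves, bands = "alpha", epoch_length_s = 6,
                            regions = NULL) {
  # curves: region x band x duration array of median ICC
  d <- dim(curves)
  if (is.null(regions)) regions <- sprintf("region_%d", seq_len(d[1]))
  dimnames(curves) <- list(regions, bands, NULL)
  structure(list(
    durations_s = seq_len(d[3]) * epoch_length_s,
    icc = curves, ci_low = curves - 0.02, ci_high = curves + 0.02,
    region_summary = NULL, regions = regions, bands = bands,
    epoch_length_s = epoch_length_s, n_permutations = 1L, n_participants = 10L
  ), class = "stability_curve")
}

test_that("threshold extraction follows the first-crossing rule with DNS coding", {
  # everywhere above 0.95: excellent reached at the first bin
  hi <- make_fake_curve(array(0.96, c(1, 1, 5)))
  tt <- threshold_durations(hi)
  expect_equal(tt$durations$duration_s[tt$durations$threshold == 0.9], 6)

  # plateau at 0.8: good finite, excellent DNS
  plat <- make_fake_curve(array(rep(c(0.6, 0.8, 0.8, 0.8), each = 1), c(1, 1, 4)))
  tp <- threshold_durations(plat)
  expect_equal(tp$durations$duration_s[tp$durations$threshold == 0.75], 12)
  expect_true(is.na(tp$durations$duration_s[tp$durations$threshold == 0.9]))
  expect_equal(tp$aggregates$median[tp$aggregates$threshold == 0.9], "DNS")

  # monotone curve: crossing durations ordered across thresholds
  mono <- make_fake_curve(array((1:8) / 8.5, c(1, 1, 8)))
  tm <- threshold_durations(mono)$durations
  d <- tm$duration_s[order(tm$threshold)]
  expect_true(all(diff(d) >= 0))

  # most/least stable regions ranked by overall ICC
  two <- make_fake_curve(array(c(rep(0.95, 3), rep(0.55, 3)), c(2, 1, 3)),
                         regions = c("strong", "weak"))
  ta <- threshold_durations(two)
  expect_equal(unique(ta$aggregates$most_stable_region), "strong")
  expect_equal(unique(ta$aggregates$least_stable_region), "weak")
})

test_that("CI overlap comparison flags only genuinely divergent analyses", {
  sp <- variance_component_spec(1, 1, n_participants = 80, n_epochs = 10, seed = 11)
  sch <- permutation_schedule(10, 30, seed = 12)
  a <- stability_curves(gen_feature_array(sp), sch)
  expect_true(all(ci_overlap(a, a)$overlap))

  # two independent draws of the same spec overlap everywhere
  sp2 <- sp; sp2$seed <- 99L
  b <- stability_curves(gen_feature_array(sp2), sch)
  expect_true(mean(ci_overlap(a, b)$overlap) >= 0.95)

  # very different within-subject noise diverges at small m
  lo_n <- stability_curves(gen_feature_array(
    variance_component_spec(1, 0.1, 80, n_epochs = 10, seed = 13)), sch)
  hi_n <- stability_curves(gen_feature_array(
    variance_component_spec(1, 10, 80, n_epochs = 10, seed = 13)), sch)
  ov <- ci_overlap(lo_n, hi_n)
  expect_false(all(ov$overlap))
  expect_gt(nrow(attr(ov, "divergent")), 0)
})

test_that("subsampling analysis tightens with sample size and skips infeasible sizes", {
  sp <- variance_component_spec(1, 1, n_participants = 60, n_regions = 3,
                                n_epochs = 10, seed = 14)
  x <- gen_feature_array(sp)
  sch <- permutation_schedule(10, 15, seed = 15)
  expect_warning(ss <- subsample_stability(x, sizes = c(5, 20, 60, 100),
                                           n_subsamples = 25, schedule = sch, seed = 16),
                 "skipping")
  expect_setequal(unique(ss$size), c(5, 20, 60))
  # the full sample admits a single draw: MAD exactly zero
  expect_true(all(ss$mad_icc[ss$size == 60] == 0))
  # across-draw dispersion shrinks with size
  expect_lt(mean(ss$mad_icc[ss$size == 20]), mean(ss$mad_icc[ss$size == 5]))
})
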