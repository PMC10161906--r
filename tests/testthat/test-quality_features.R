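seg_of <- function(s, mb = 3) segment_first_pass(s, min_baseline = mb)

test_that("signal drop uses the 3-point minimum mean against the baseline", {
  s <- example_course()
  expect_equal(signal_drop(s, seg_of(s)), 100 - mean(c(70, 60, 70)),
               tolerance = 1e-12)
  # additive offsets cancel
  s2 <- example_course(offset = 250)
  expect_equal(signal_drop(s2, seg_of(s2)), 100 - mean(c(70, 60, 70)),
               tolerance = 1e-12)
})

test_that("SDNR matches hand arithmetic and is scale invariant", {
  s <- noisy_baseline_course()
  seg <- seg_of(s)
  expect_equal(sd(s$values[1:5]), 1)
  expect_equal(sdnr(s, seg), 100 - mean(c(70, 60, 70)), tolerance = 1e-12)

  s2 <- signal_timecourse(3.7 * s$values, 1)
  expect_equal(sdnr(s2, seg_of(s2)), sdnr(s, seg), tolerance = 1e-12)

  # noiseless baseline has zero SD
  s0 <- example_course()
  expect_error(sdnr(s0, seg_of(s0)), class = "dscqc_degenerate_baseline")
})

test_that("FWHM interpolates the half-level crossings", {
  s <- noisy_baseline_course(tr = 1)
  seg <- seg_of(s)
  # half level 83.333: left crossing 6.333, right crossing 9.667
  expect_equal(fwhm(s, seg), 10 / 3, tolerance = 1e-9)
  # linear in TR
  s2 <- noisy_baseline_course(tr = 2)
  expect_equal(fwhm(s2, seg_of(s2)), 20 / 3, tolerance = 1e-9)
  # invariant under affine intensity maps
  s3 <- signal_timecourse(0.25 * s$values + 40, 1)
  expect_equal(fwhm(s3, seg_of(s3)), fwhm(s, seg), tolerance = 1e-9)
})

test_that("PSR reflects the post-bolus plateau level", {
  s <- example_course()
  expect_equal(psr(s, seg_of(s)), 100, tolerance = 1e-12)

  # plateau at 90: PSR = 100 * 23.333 / 33.333 = 70
  s70 <- signal_timecourse(c(rep(100, 5), 90, 70, 60, 70, rep(90, 6)), 1)
  expect_equal(psr(s70, seg_of(s70)), 70, tolerance = 1e-9)

  # overshoot above baseline gives PSR > 100 (T1-contamination morphology)
  sov <- signal_timecourse(c(rep(100, 5), 90, 70, 60, 70, 90, rep(110, 5)), 1)
  expect_gt(psr(sov, seg_of(sov)), 100)
})

test_that("gamma-variate fit recovers noiseless parameters", {
  tr <- 1
  t <- (0:29) * tr
  v <- 100 - 5 * ifelse(t - 5 > 0, (t - 5)^1.5 * exp(-(t - 5) / 2), 0)
  s <- signal_timecourse(v, tr)
  seg <- seg_of(s)
  fit <- fit_gamma_variate(s, seg)
  expect_true(fit$converged)
  expect_equal(fit$K, 5, tolerance = 1e-4)
  expect_equal(fit$alpha, 1.5, tolerance = 1e-4)
  expect_equal(fit$beta, 2, tolerance = 1e-4)
  expect_lt(fit$rmse_norm, 1e-6)
})

test_that("added noise increases the normalised RMSE on the same curve", {
  p0 <- course_params(s0 = 1000, sigma = 0, t0 = 20, alpha = 2, beta = 3,
                      depth = 300, psr_true = 100, n_dynamics = 50,
                      tr_seconds = 2)
  s0 <- simulate_timecourse(p0, 1)$signal
  seg <- segment_first_pass(s0)
  base <- fit_gamma_variate(s0, seg)$rmse_norm
  set.seed(4)
  worse <- replicate(5, {
    noisy <- signal_timecourse(s0$values + rnorm(50, 0, 150), 2)
    fit_gamma_variate(noisy, seg)$rmse_norm
  })
  expect_true(all(worse > base))
})

test_that("normalised RMSE is affine invariant", {
  p <- course_params(sigma = 20)
  s <- simulate_timecourse(p, 9)$signal
  seg <- segment_first_pass(s)
  r1 <- fit_gamma_variate(s, seg)$rmse_norm
  s2 <- signal_timecourse(5 * s$values + 100, s$tr_seconds)
  r2 <- fit_gamma_variate(s2, segment_first_pass(s2))$rmse_norm
  expect_equal(r2, r1, tolerance = 1e-4)
})

test_that("best fit beats a coarse grid of fixed candidates", {
  p <- course_params(sigma = 15)
  s <- simulate_timecourse(p, 13)$signal
  seg <- segment_first_pass(s)
  fit <- fit_gamma_variate(s, seg)
  expect_true(fit$converged)

  fp <- seg$first_pass
  t <- (fp - seg$baseline_end) * s$tr_seconds
  cbase <- mean(s$values[1:seg$baseline_end])
  drop <- cbase - s$values[fp]
  sse_best <- sum((drop - (cbase - fit$fitted))^2)
  for (K in c(50, 150, 400)) for (a in c(1, 2, 3)) for (b in c(1, 3, 6)) {
    cand <- K * ifelse(t > 0, t^a * exp(-t / b), 0)
    expect_gte(sum((drop - cand)^2), sse_best - 1e-6)
  }
})

test_that("extract_features composes the measures with validity flags", {
  f <- extract_features(noisy_baseline_course(), min_baseline = 3)
  expect_true(f$valid)
  expect_equal(f$sdnr, 100 / 3, tolerance = 1e-6)
  expect_equal(f$fwhm_s, 10 / 3, tolerance = 1e-6)
  expect_equal(f$psr_pct, 100, tolerance = 1e-6)
  expect_true(is.finite(f$rmse_norm))

  # constant signal: whole voxel invalid with the segmentation reason
  fc <- extract_features(signal_timecourse(rep(100, 20), 1))
  expect_false(fc$valid)
  expect_match(fc$reason, "no_bolus")

  # per-measure failure (zero baseline SD) flags only that measure
  f0 <- extract_features(example_course(), min_baseline = 3)
  expect_true(f0$valid)
  expect_true(is.na(f0$sdnr))
  expect_false(is.na(f0$psr_pct))
  expect_match(f0$reason, "degenerate_baseline")
})

test_that("feature_table is order preserving and handles empty input", {
  co <- simulate_cohort(25, seed = 2)
  ft <- feature_table(co$signals)
  expect_identical(nrow(ft), 25L)
  expect_identical(ft$voxel_id, as.character(1:25))
  expect_identical(nrow(feature_table(list())), 0L)
})

test_that("all four measures are invariant under random affine maps", {
  co <- simulate_cohort(40, seed = 41)
  set.seed(41)
  checked <- 0L
  for (s in co$signals) {
    f1 <- extract_features(s)
    if (!f1$valid || anyNA(f1[c("sdnr", "fwhm_s", "psr_pct", "rmse_norm")])) next
    a <- stats::runif(1, 0.2, 8); c0 <- stats::runif(1, -300, 300)
    s2 <- signal_timecourse(a * s$values + c0, s$tr_seconds)
    f2 <- extract_features(s2)
    expect_equal(f2$sdnr, f1$sdnr, tolerance = 1e-8)
    expect_equal(f2$fwhm_s, f1$fwhm_s, tolerance = 1e-8)
    expect_equal(f2$psr_pct, f1$psr_pct, tolerance = 1e-8)
    expect_equal(f2$rmse_norm, f1$rmse_norm, tolerance = 1e-3)
    checked <- checked + 1L
  }
  expect_gt(checked, 8L)
})

test_that("SDNR and PSR ignore TR while FWHM scales with it", {
  v <- noisy_baseline_course(tr = 1)$values
  f1 <- extract_features(signal_timecourse(v, 1), min_baseline = 3)
  f2 <- extract_features(signal_timecourse(v, 3), min_baseline = 3)
  expect_equal(f2$sdnr, f1$sdnr)
  expect_equal(f2$psr_pct, f1$psr_pct)
  expect_equal(f2$fwhm_s, 3 * f1$fwhm_s, tolerance = 1e-9)
})
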