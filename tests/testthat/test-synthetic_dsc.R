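test_that("course_params validates invariants", {
  expect_error(course_params(s0 = -1), class = "dscqc_invalid_params")
  expect_error(course_params(psr_true = 250), class = "dscqc_invalid_params")
  expect_error(course_params(t0 = 2, tr_seconds = 2), class = "dscqc_invalid_params")
  expect_s3_class(course_params(), "course_params")
})

test_that("noiseless courses round-trip through the measures", {
  p <- course_params(sigma = 0, psr_true = 85)
  sim <- simulate_timecourse(p, 5)
  f <- extract_features(sim$signal)
  expect_true(f$valid)
  # FWHM within one linear-interpolation step (one TR), PSR within 1% absolute
  expect_lt(abs(f$fwhm_s - sim$truth$fwhm_true), p$tr_seconds)
  expect_lt(abs(f$psr_pct - sim$truth$psr_true), 1)
})

test_that("same params and seed give byte-identical output", {
  p <- course_params(sigma = 25, artifact = artifact_spikes())
  s1 <- simulate_timecourse(p, 77)
  s2 <- simulate_timecourse(p, 77)
  expect_identical(s1$signal$values, s2$signal$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_timecourse(p, 78)
  expect_false(identical(s1$signal$values, s3$signal$values))

  co1 <- simulate_cohort(30, seed = 4)
  co2 <- simulate_cohort(30, seed = 4)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$signals[[7]]$values, co2$signals[[7]]$values)
})

test_that("mean measured SDNR converges to depth/sigma (3 SE, n = 500)", {
  # Gradual-onset world with long baselines; k_sigma = 1.5 so detection is
  # not systematically late (see vignette). True SDNR = 30 / 3 = 10.
  seeds <- derive_seeds(42, 500)
  vals <- vapply(seeds, function(sd) {
    p <- course_params(s0 = 1000, sigma = 3, t0 = 80, alpha = 1, beta = 6,
                       depth = 30, psr_true = 100, n_dynamics = 86,
                       tr_seconds = 2)
    extract_features(simulate_timecourse(p, sd)$signal, k_sigma = 1.5)$sdnr
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 10), 3 * se)
})

test_that("measured FWHM and PSR errors shrink monotonically as noise drops", {
  base <- course_params(sigma = 0, psr_true = 80, n_dynamics = 80,
                        tr_seconds = 1.5, t0 = 15)
  truth <- simulate_timecourse(base, 1)$truth
  err <- vapply(c(1, 0.1, 0), function(sig) {
    p <- base; p$sigma <- sig * 30
    fs <- vapply(derive_seeds(8, 40), function(sd) {
      f <- extract_features(simulate_timecourse(p, sd)$signal, k_sigma = 1.5)
      c(f$fwhm_s, f$psr_pct)
    }, numeric(2))
    mean(abs(fs[1, ] - truth$fwhm_true), na.rm = TRUE) +
      mean(abs(fs[2, ] - truth$psr_true), na.rm = TRUE) / 10
  }, numeric(1))
  # adjacent steps allow a small sampling-noise margin; the overall trend
  # from sigma = 1 down to 0 must be strictly decreasing
  expect_gte(err[1], err[2] - 0.05)
  expect_gte(err[2], err[3] - 0.05)
  expect_gt(err[1], err[3])
})

test_that("cohort labels are a pure function of truths and rule", {
  co <- simulate_cohort(100, seed = 14)
  rule <- co$spec$rule
  relabel <- with(co$truth,
    as.integer(sdnr_true >= rule$sdnr_min &
               is.finite(fwhm_true) &
               fwhm_true >= rule$fwhm_range[1] & fwhm_true <= rule$fwhm_range[2] &
               psr_true >= rule$psr_range[1] & psr_true <= rule$psr_range[2]))
  expect_identical(relabel, co$truth$qr_label)
})

test_that("default cohort hits the target pass rate within 10%", {
  co <- simulate_cohort(600, seed = 2)
  expect_gt(mean(co$truth$qr_label), 0.7 * 0.9)
  expect_lt(mean(co$truth$qr_label), 0.7 * 1.1)
})

test_that("artifact-free permissive rule passes everything", {
  sp <- cohort_spec(artifact_probs = c(none = 1, spikes = 0,
                                       first_pass_noise = 0, narrow = 0,
                                       shallow = 0),
                    rule = list(sdnr_min = 0))
  co <- simulate_cohort(40, seed = 6, spec = sp)
  expect_true(all(co$truth$qr_label == 1L))
  expect_error(simulate_cohort(10, seed = 1), class = "dscqc_invalid_params")
})

test_that("two seeds differ per course but agree in distribution", {
  a <- simulate_cohort(300, seed = 101)
  b <- simulate_cohort(300, seed = 202)
  expect_false(identical(a$signals[[1]]$values, b$signals[[1]]$values))
  # same stated world: pass rates and truth means agree within tolerance
  expect_lt(abs(mean(a$truth$qr_label) - mean(b$truth$qr_label)), 0.1)
  expect_lt(abs(mean(a$truth$psr_true) - mean(b$truth$psr_true)), 5)
})

test_that("artifacts corrupt the sampled signal as described", {
  p_clean <- course_params(sigma = 10)
  p_spike <- course_params(sigma = 10, artifact = artifact_spikes(count = 3, amplitude = 400))
  s_clean <- simulate_timecourse(p_clean, 55)$signal$values
  s_spike <- simulate_timecourse(p_spike, 55)$signal$values
  expect_identical(sum(abs(s_spike - s_clean) > 300), 3L)

  p_noise <- course_params(sigma = 10, artifact = artifact_first_pass_noise(extra_sd = 100))
  s_noise <- simulate_timecourse(p_noise, 55)$signal$values
  changed <- which(abs(s_noise - s_clean) > 1e-9)
  t <- (seq_along(s_clean) - 1) * p_clean$tr_seconds
  expect_true(all(t[changed] > p_clean$t0))

  # narrow shrinks true FWHM; shallow shrinks true SDNR
  tr_narrow <- simulate_timecourse(course_params(sigma = 10, artifact = artifact_narrow()), 55)$truth
  tr_shallow <- simulate_timecourse(course_params(sigma = 10, artifact = artifact_shallow()), 55)$truth
  tr_base <- simulate_timecourse(p_clean, 55)$truth
  expect_lt(tr_narrow$fwhm_true, tr_base$fwhm_true / 2)
  expect_equal(tr_shallow$sdnr_true, 0.2 * tr_base$sdnr_true, tolerance = 1e-9)
})
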