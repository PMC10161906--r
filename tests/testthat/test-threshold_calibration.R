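test_that("crossing threshold matches the exhaustive-scan examples", {
  # pass {10,12,14} vs fail {2,4,20}: theta = 12 gives sens = spec = 2/3
  expect_equal(crossing_threshold(c(10, 12, 14, 2, 4, 20),
                                  c(1, 1, 1, 0, 0, 0), "higher_is_better"), 12)
  # perfectly separated: smallest candidate achieving sens = spec = 1
  expect_equal(crossing_threshold(c(8, 9, 10, 1, 2, 3),
                                  c(1, 1, 1, 0, 0, 0), "higher_is_better"), 8)
  # inverted labels with flipped orientation mirror the threshold
  expect_equal(crossing_threshold(c(8, 9, 10, 1, 2, 3),
                                  c(0, 0, 0, 1, 1, 1), "lower_is_better"), 3)
  expect_error(crossing_threshold(c(1, 2, 3), c(1, 1, 1), "higher_is_better"),
               class = "dscqc_single_class")
})

test_that("crossing threshold is optimal against brute force on random data", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    v <- round(rnorm(n), 2)
    l <- rbinom(n, 1, 0.5)
    if (sum(l) < 2 || sum(1 - l) < 2) next
    or <- sample(c("higher_is_better", "lower_is_better"), 1)
    th <- crossing_threshold(v, l, or)
    pass <- if (or == "higher_is_better") v >= th else v <= th
    gap <- abs(sum(pass & l == 1) / sum(l) - sum(!pass & l == 0) / sum(1 - l))
    expect_equal(gap, crossing_oracle_gap(v, l, or), tolerance = 1e-12)
  }
})

test_that("range thresholds bracket the passing values", {
  # the published FWHM endpoints come from passing values at 3 and 19 s
  v <- c(1.8, 3, 7, 19, 25)
  l <- c(0, 1, 1, 1, 0)
  expect_equal(unname(range_thresholds(v, l)), c(3, 19))
  expect_equal(unname(range_thresholds(c(2, 5, 9), c(1, 1, 1))), c(2, 9))
  expect_equal(unname(range_thresholds(c(2, 5, 9), c(0, 1, 0))), c(5, 5))
  expect_error(range_thresholds(c(1, 2), c(0, 0)), class = "dscqc_no_passing")
})

test_that("range rule never rejects a training passing example", {
  set.seed(12)
  for (rep in 1:20) {
    v <- runif(30, 0, 50)
    l <- rbinom(30, 1, 0.6)
    if (!any(l == 1)) next
    r <- range_thresholds(v, l)
    expect_true(all(v[l == 1] >= r[1] & v[l == 1] <= r[2]))
  }
})

test_that("stratified folds partition records with balanced classes", {
  set.seed(3)
  labels <- rbinom(137, 1, 0.7)
  fold <- make_stratified_folds(labels, 10, seed = 5)
  expect_true(all(fold %in% 1:10))
  expect_identical(length(fold), length(labels))
  # per-fold positive counts within one record of the balanced share
  pos_per_fold <- tapply(labels, fold, sum)
  expect_lte(diff(range(pos_per_fold)), 1)
  n_per_fold <- tabulate(fold, 10)
  expect_lte(diff(range(n_per_fold)), 2)
  expect_error(make_stratified_folds(c(rep(1, 5), rep(0, 50)), 10, 1),
               class = "dscqc_insufficient_class")
})

test_that("calibrate_kfold is deterministic and respects preconditions", {
  tab <- gaussian_feature_table(120, sep = 3, seed = 2)
  t1 <- calibrate_kfold(tab, k = 5, seed = 9)
  t2 <- calibrate_kfold(tab, k = 5, seed = 9)
  expect_identical(t1, t2)
  t3 <- calibrate_kfold(tab, k = 5, seed = 10)
  expect_false(identical(t1$per_fold, t3$per_fold))

  few <- tab[c(which(tab$qr_label == 1)[1:5], which(tab$qr_label == 0)), ]
  expect_error(calibrate_kfold(few, k = 10, seed = 1),
               class = "dscqc_insufficient_class")
})

test_that("headline thresholds are fold means and calibration is equivariant", {
  tab <- gaussian_feature_table(200, sep = 3, seed = 7)
  ts <- calibrate_kfold(tab, k = 10, seed = 7)
  expect_equal(ts$sdnr_min, mean(ts$per_fold$sdnr_min))
  expect_equal(ts$fwhm_range, c(mean(ts$per_fold$fwhm_low),
                                mean(ts$per_fold$fwhm_high)))
  expect_identical(nrow(ts$per_fold), 10L)

  # multiplying a measure by a > 0 multiplies its thresholds by a
  tab2 <- tab
  tab2$sdnr <- 3.5 * tab$sdnr
  tab2$fwhm_s <- 0.4 * tab$fwhm_s
  ts2 <- calibrate_kfold(tab2, k = 10, seed = 7)
  expect_equal(ts2$sdnr_min, 3.5 * ts$sdnr_min, tolerance = 1e-12)
  expect_equal(ts2$fwhm_range, 0.4 * ts$fwhm_range, tolerance = 1e-12)
})

test_that("apply_thresholds follows the orientation and inclusivity rules", {
  thr <- read_thresholds(system.file("extdata", "default_thresholds.json",
                                     package = "dscqc"))
  feats <- data.frame(sdnr = c(33.33, 5.0), rmse_norm = c(0.01, 0.05),
                      fwhm_s = c(2.0, 19), psr_pct = c(130.4, 42.89),
                      valid = TRUE, reason = "")
  expect_identical(apply_thresholds(feats, thr, "sdnr")$pass, c(TRUE, FALSE))
  expect_identical(apply_thresholds(feats, thr, "rmse")$pass, c(TRUE, FALSE))
  expect_identical(apply_thresholds(feats, thr, "fwhm")$pass, c(FALSE, TRUE))
  # inclusive at both range ends; just below the lower end fails
  expect_identical(apply_thresholds(feats, thr, "psr")$pass, c(TRUE, FALSE))

  bad <- data.frame(sdnr = NA_real_, rmse_norm = 0.01, fwhm_s = 5,
                    psr_pct = 80, valid = FALSE, reason = "dscqc_no_bolus")
  out <- apply_thresholds(bad, thr, "sdnr")
  expect_false(out$pass)
  expect_match(out$reason, "no_bolus")
})

test_that("threshold sets round-trip through JSON", {
  tab <- gaussian_feature_table(100, sep = 3, seed = 4)
  ts <- calibrate_kfold(tab, k = 5, seed = 4)
  path <- tempfile(fileext = ".json")
  write_thresholds(ts, path)
  back <- read_thresholds(path)
  expect_equal(back$sdnr_min, ts$sdnr_min)
  expect_equal(back$rmse_max, ts$rmse_max)
  expect_equal(back$fwhm_range, ts$fwhm_range)
  expect_equal(back$psr_range, ts$psr_range)
})

test_that("pooled confusion metrics equal count-weighted fold means", {
  set.seed(6)
  folds <- lapply(1:5, function(f) {
    n <- sample(30:60, 1)
    list(pred = rbinom(n, 1, 0.6), truth = rbinom(n, 1, 0.6))
  })
  cts <- lapply(folds, function(f) confusion_table(f$pred, f$truth))
  pooled <- confusion_table(unlist(lapply(folds, `[[`, "pred")),
                            unlist(lapply(folds, `[[`, "truth")))
  mp <- binary_metrics(pooled)
  sens_f <- vapply(cts, function(ct) binary_metrics(ct)$sensitivity, numeric(1))
  wts <- vapply(cts, function(ct) ct$tp + ct$fn, numeric(1))
  expect_equal(mp$sensitivity, sum(sens_f * wts) / sum(wts), tolerance = 1e-12)
  err_f <- vapply(cts, function(ct) binary_metrics(ct)$classification_error, numeric(1))
  n_f <- vapply(cts, function(ct) ct$tp + ct$fp + ct$fn + ct$tn, numeric(1))
  expect_equal(mp$classification_error, sum(err_f * n_f) / sum(n_f), tolerance = 1e-12)
})
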