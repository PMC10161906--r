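#' Stratified fold assignment
#'
#' Shuffles record indices within each class using the given seed, then deals
#' them round-robin into `k` folds, so per-fold class proportions are within
#' one record of the global proportions. This exact assignment is used by
#' both threshold calibration and classifier cross-validation.
#'
#' @param labels binary labels (1 = accepted).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, one per record.
#' @export
make_stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(as.logical(labels))
  k <- as.integer(k)
  if (any(table(factor(labels, levels = 0:1)) < k))
    qc_abort(sprintf("insufficient class counts for %d folds", k),
             "dscqc_insufficient_class")
  fold <- integer(length(labels))
  rng <- local_rng(seed)
  for (cls in c(1L, 0L)) {
    idx <- which(labels == cls)
    idx <- idx[rng$sample_perm(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Self-contained RNG scope: seeds .Random.seed locally and restores the
# caller's RNG state on exit of the *calling* function... R has no such hook
# outside withr, so instead we snapshot and restore eagerly around each draw
# batch. All package randomness goes through these helpers.
local_rng <- function(seed) {
  draw <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    out <- f()
    # advance the stream so consecutive draws differ
    seed <<- sample.int(.Machine$integer.max, 1L)
    out
  }
  list(
    sample_perm = function(n) draw(function() sample.int(n)),
    runif = function(n, min = 0, max = 1) draw(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) draw(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size, replace = FALSE)
      draw(function() sample.int(n, size, replace = replace)),
    next_seed = function() draw(function() sample.int(2^31 - 2, 1L))
  )
}

#' Derive a deterministic stream of child seeds from one top-level seed
#'
#' @param seed top-level integer seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  rng <- local_rng(seed)
  vapply(seq_len(n), function(i) rng$next_seed(), integer(1L))
}

#' Sensitivity-equals-specificity crossing threshold
#'
#' Sweeps candidate thresholds over the sorted unique observed values and
#' returns the threshold where training sensitivity and specificity are
#' closest. A record passes when its value is `>= threshold`
#' (`higher_is_better`) or `<= threshold` (`lower_is_better`). Ties on
#' `|sens - spec|` are broken by larger `sens + spec`, then by smaller
#' threshold.
#'
#' @param values numeric measure values.
#' @param labels binary quality labels (1 = accepted).
#' @param orientation `"higher_is_better"` (SDNR) or `"lower_is_better"`
#'   (RMSE).
#' @return the selected threshold (one of the observed values).
#' @export
crossing_threshold <- function(values, labels,
                               orientation = c("higher_is_better", "lower_is_better")) {
  orientation <- match.arg(orientation)
  labels <- as.integer(as.logical(labels))
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    qc_abort("single-class input (need >= 2 values per class)", "dscqc_single_class")
  cand <- sort(unique(values))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  best <- NULL
  for (th in cand) {
    pass <- if (orientation == "higher_is_better") values >= th else values <= th
    sens <- sum(pass & labels == 1L) / n1
    spec <- sum(!pass & labels == 0L) / n0
    key <- c(abs(sens - spec), -(sens + spec), th)
    if (is.null(best) || key[1L] < best$key[1L] ||
        (key[1L] == best$key[1L] && (key[2L] < best$key[2L] ||
         (key[2L] == best$key[2L] && key[3L] < best$key[3L])))) {
      best <- list(key = key, th = th)
    }
  }
  best$th
}

#' Range thresholds from the passing examples
#'
#' The lower and upper thresholds are the smallest and largest measure values
#' that passed qualitative review; application is inclusive at both ends, so
#' no training passing example is ever rejected.
#'
#' @inheritParams crossing_threshold
#' @return numeric `c(low, high)`.
#' @export
range_thresholds <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  pass <- values[labels == 1L]
  if (length(pass) == 0L)
    qc_abort("no passing examples", "dscqc_no_passing")
  c(low = min(pass), high = max(pass))
}

measure_orientations <- list(
  sdnr = "higher_is_better",
  rmse = "lower_is_better",
  fwhm = "range",
  psr = "range"
)

measure_column <- c(sdnr = "sdnr", rmse = "rmse_norm", fwhm = "fwhm_s", psr = "psr_pct")

# Pass/fail for one measure given fitted thresholds (list as in threshold_set).
apply_measure_rule <- function(values, thresholds, measure) {
  switch(measure,
    sdnr = values >= thresholds$sdnr_min,
    rmse = values <= thresholds$rmse_max,
    fwhm = values >= thresholds$fwhm_range[1L] & values <= thresholds$fwhm_range[2L],
    psr = values >= thresholds$psr_range[1L] & values <= thresholds$psr_range[2L],
    qc_abort(sprintf("unknown measure '%s'", measure), "dscqc_unknown_measure")
  )
}

# Continuous score for ROC sweeping of a measure rule. For one-sided rules
# the measure itself (sign-flipped for lower-is-better); for range rules a
# single symmetric inflation factor around the training range is swept,
# i.e. score = -|v - mid| / halfwidth.
measure_score <- function(values, thresholds, measure) {
  switch(measure,
    sdnr = values,
    rmse = -values,
    fwhm = {
      r <- thresholds$fwhm_range
      -abs(values - mean(r)) / max((r[2L] - r[1L]) / 2, .Machine$double.eps)
    },
    psr = {
      r <- thresholds$psr_range
      -abs(values - mean(r)) / max((r[2L] - r[1L]) / 2, .Machine$double.eps)
    }
  )
}

fit_measure_threshold <- function(values, labels, measure) {
  or <- measure_orientations[[measure]]
  if (or == "range") range_thresholds(values, labels)
  else crossing_threshold(values, labels, or)
}

#' Calibrate quality thresholds by stratified k-fold cross-validation
#'
#' For each fold, thresholds for each measure are fitted on the k-1 training
#' folds (sensitivity-equals-specificity crossing for SDNR and RMSE; the
#' passed-example range for FWHM and PSR) and performance metrics computed on
#' the held-out fold. Headline thresholds and metrics are fold means; the
#' per-fold values are retained for provenance. Stratification is by label
#' only (signal basis, not subject basis). Rows with a missing value for a
#' measure are excluded from that measure's fit and evaluation.
#'
#' @param table a `data.frame` with feature columns `sdnr`, `rmse_norm`,
#'   `fwhm_s`, `psr_pct` and a binary column `qr_label` (1 = accepted).
#' @param k fold count (default 10).
#' @param seed integer seed controlling the fold shuffle.
#' @return an object of class `threshold_set`: headline `sdnr_min`,
#'   `rmse_max`, `fwhm_range`, `psr_range`; `per_fold` data.frame;
#'   `metrics` (per-measure mean [binary_metrics()] including AUC);
#'   `per_fold_metrics`; `k`; `seed`.
#' @export
calibrate_kfold <- function(table, k = 10L, seed = 1L) {
  stopifnot(is.data.frame(table), "qr_label" %in% names(table))
  labels <- as.integer(as.logical(table$qr_label))
  fold <- make_stratified_folds(labels, k, seed)
  measures <- names(measure_column)

  per_fold <- list()
  per_fold_metrics <- list()
  for (f in seq_len(k)) {
    train <- fold != f
    thr <- list()
    for (m in measures) {
      v <- table[[measure_column[[m]]]]
      ok <- train & is.finite(v)
      fitted <- fit_measure_threshold(v[ok], labels[ok], m)
      thr[[switch(m, sdnr = "sdnr_min", rmse = "rmse_max",
                  fwhm = "fwhm_range", psr = "psr_range")]] <- fitted
    }
    per_fold[[f]] <- data.frame(
      fold = f, sdnr_min = thr$sdnr_min, rmse_max = thr$rmse_max,
      fwhm_low = thr$fwhm_range[1L], fwhm_high = thr$fwhm_range[2L],
      psr_low = thr$psr_range[1L], psr_high = thr$psr_range[2L]
    )
    mrows <- lapply(measures, function(m) {
      v <- table[[measure_column[[m]]]]
      ok <- !train & is.finite(v)
      pred <- apply_measure_rule(v[ok], thr, m)
      ms <- binary_metrics(confusion_table(pred, labels[ok]))
      auc <- tryCatch(roc_auc(measure_score(v[ok], thr, m), labels[ok]),
                      dscqc_error = function(e) NA_real_)
      data.frame(fold = f, measure = m, sensitivity = ms$sensitivity,
                 specificity = ms$specificity, precision = ms$precision,
                 classification_error = ms$classification_error, auc = auc,
                 stringsAsFactors = FALSE)
    })
    per_fold_metrics[[f]] <- do.call(rbind, mrows)
  }
  per_fold <- do.call(rbind, per_fold)
  per_fold_metrics <- do.call(rbind, per_fold_metrics)

  mean_metrics <- do.call(rbind, lapply(measures, function(m) {
    sub <- per_fold_metrics[per_fold_metrics$measure == m, ]
    data.frame(measure = m,
               sensitivity = mean(sub$sensitivity, na.rm = TRUE),
               specificity = mean(sub$specificity, na.rm = TRUE),
               precision = mean(sub$precision, na.rm = TRUE),
               classification_error = mean(sub$classification_error, na.rm = TRUE),
               auc = mean(sub$auc, na.rm = TRUE), stringsAsFactors = FALSE)
  }))

  structure(
    list(sdnr_min = mean(per_fold$sdnr_min),
         rmse_max = mean(per_fold$rmse_max),
         fwhm_range = c(mean(per_fold$fwhm_low), mean(per_fold$fwhm_high)),
         psr_range = c(mean(per_fold$psr_low), mean(per_fold$psr_high)),
         per_fold = per_fold, metrics = mean_metrics,
         per_fold_metrics = per_fold_metrics, k = k, seed = seed),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(paste0("<threshold_set (k = %d): SDNR >= %.3g, RMSE <= %.3g,\n",
                     "  FWHM in [%.3g, %.3g] s, PSR in [%.3g, %.3g]%%>\n"),
              x$k, x$sdnr_min, x$rmse_max, x$fwhm_range[1L], x$fwhm_range[2L],
              x$psr_range[1L], x$psr_range[2L]))
  invisible(x)
}

#' Apply calibrated thresholds to a feature table
#'
#' A row passes when `sdnr >= sdnr_min` (SDNR rule), `rmse_norm <= rmse_max`
#' (RMSE rule) or its value lies inside the inclusive FWHM/PSR range. Invalid
#' or missing features fail with a reason, never error.
#'
#' @param features a feature table ([feature_table()]) or one-row
#'   `data.frame`.
#' @param thresholds a `threshold_set` (or a list with the same fields, e.g.
#'   from [read_thresholds()]).
#' @param measure which rule to apply: `"sdnr"`, `"rmse"`, `"fwhm"` or
#'   `"psr"`.
#' @return a `data.frame` with columns `pass` (logical) and `reason`.
#' @export
apply_thresholds <- function(features, thresholds,
                             measure = c("sdnr", "rmse", "fwhm", "psr")) {
  measure <- match.arg(measure)
  v <- features[[measure_column[[measure]]]]
  pass <- rep(FALSE, length(v))
  reason <- rep("", length(v))
  bad <- !is.finite(v)
  if ("valid" %in% names(features)) bad <- bad | !features$valid
  pass[!bad] <- apply_measure_rule(v[!bad], thresholds, measure)
  reason[bad] <- if ("reason" %in% names(features))
    ifelse(nzchar(features$reason[bad]), features$reason[bad], "missing measure")[seq_len(sum(bad))]
  else "missing measure"
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Write / read a threshold set as JSON
#'
#' The shipped default config (`system.file("extdata",
#' "default_thresholds.json", package = "dscqc")`) contains published
#' cohort-specific values (SDNR 7.6, RMSE 0.019, FWHM 3-19 s, PSR
#' 42.9-130.4%) and should be recalibrated for any new protocol.
#'
#' @param thresholds a `threshold_set` or compatible list.
#' @param path file path.
#' @return `path` invisibly / the threshold list.
#' @export
write_thresholds <- function(thresholds, path) {
  out <- list(sdnr_min = thresholds$sdnr_min, rmse_max = thresholds$rmse_max,
              fwhm_range = thresholds$fwhm_range, psr_range = thresholds$psr_range,
              k = thresholds$k %||% NA, seed = thresholds$seed %||% NA)
  if (!is.null(thresholds$per_fold)) out$per_fold <- thresholds$per_fold
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$fwhm_range <- as.numeric(x$fwhm_range)
  x$psr_range <- as.numeric(x$psr_range)
  class(x) <- "threshold_set"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
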