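#' Construct a signal-time course
#'
#' A signal-time course is one voxel's signal intensity across the dynamics
#' (time points) of a DSC-MRI acquisition, together with the repetition time
#' TR that converts dynamic indices to seconds. All indices reported by this
#' package are 1-based and inclusive.
#'
#' @param values numeric vector of signal intensities, one per dynamic
#'   (arbitrary scanner units); at least 12 dynamics, all finite.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param voxel_id optional identifier: either a single row index or an
#'   integer triple `(i, j, k)` of 0-based spatial indices.
#' @return an object of class `signal_timecourse`.
#' @examples
#' s <- signal_timecourse(c(rep(100, 5), 90, 70, 60, 70, 90, rep(100, 5)), 1)
#' segment_first_pass(s, min_baseline = 3)
#' @export
signal_timecourse <- function(values, tr_seconds, voxel_id = NULL) {
  values <- as.numeric(values)
  if (length(values) < 12L)
    qc_abort("series too short: need at least 12 dynamics", "dscqc_too_short")
  if (!all(is.finite(values)))
    qc_abort("signal values must be finite", "dscqc_invalid_signal")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0)
    qc_abort("tr_seconds must be a single positive number", "dscqc_invalid_signal")
  structure(
    list(values = values, tr_seconds = as.numeric(tr_seconds),
         voxel_id = voxel_id),
    class = "signal_timecourse"
  )
}

#' @export
print.signal_timecourse <- function(x, ...) {
  cat(sprintf("<signal_timecourse: %d dynamics, TR = %g s>\n",
              length(x$values), x$tr_seconds))
  invisible(x)
}

#' @export
length.signal_timecourse <- function(x) length(x$values)

as_signal <- function(x) {
  if (inherits(x, "signal_timecourse")) return(x)
  qc_abort("expected a signal_timecourse", "dscqc_invalid_signal")
}

# Divergence scan shared by both plateau detectors. Operates on a plain
# numeric vector; returns the last index before the first divergence of the
# trailing 3-point moving mean from the cumulative mean of all earlier
# dynamics. Divergence at the smallest i >= max(min_baseline + 1, 3) with
#   |mm_i - cm_{i-1}| > max(k_sigma * sd_{i-1}, 1e-6 * |cm_{i-1}|)
# where sd uses the n-1 denominator; the epsilon floor guards noiseless
# signals whose baseline SD is exactly zero.
divergence_scan <- function(values, min_baseline, k_sigma) {
  n <- length(values)
  if (min_baseline < 3L)
    qc_abort("series too short: min_baseline must be >= 3", "dscqc_too_short")
  if (n < 2L * min_baseline)
    qc_abort("series too short: need n >= 2 * min_baseline", "dscqc_too_short")
  start <- max(min_baseline + 1L, 3L)
  # last usable i: divergence must occur before dynamic n - 3
  last <- n - 3L
  if (start > last)
    qc_abort("no bolus detected", "dscqc_no_bolus")
  cs <- cumsum(values)
  css <- cumsum(values^2)
  for (i in start:last) {
    m <- i - 1L
    cm <- cs[m] / m
    # sample variance of dynamics 1..m, guarded against negative round-off
    v <- max((css[m] - m * cm^2) / (m - 1L), 0)
    mm <- (values[i] + values[i - 1L] + values[i - 2L]) / 3
    if (abs(mm - cm) > max(k_sigma * sqrt(v), 1e-6 * abs(cm)))
      return(i - 1L)
  }
  qc_abort("no bolus detected", "dscqc_no_bolus")
}

#' Detect the end of the pre-bolus baseline
#'
#' Finds the last baseline dynamic by comparing a trailing moving mean
#' (window of three dynamics) with the cumulative mean of all preceding
#' dynamics, scanning from the start of the series; the baseline ends just
#' before the first dynamic where the two means diverge. "Diverged" is
#' quantified adaptively as a multiple `k_sigma` of the running baseline
#' standard deviation, with a tiny relative floor so that noiseless signals
#' still trigger. The rule is invariant under affine intensity transforms
#' `s -> a * s + c` (a > 0).
#'
#' @param signal a [signal_timecourse].
#' @param min_baseline minimum number of baseline dynamics assumed present
#'   (>= 3; default 5, tolerating the short baselines of fast protocols while
#'   keeping a usable SD estimate).
#' @param k_sigma divergence multiplier on the running baseline SD.
#' @return 1-based index of the last baseline dynamic.
#' @seealso [detect_postbolus_start()], [segment_first_pass()]
#' @export
detect_baseline_end <- function(signal, min_baseline = 5L, k_sigma = 2.5) {
  signal <- as_signal(signal)
  divergence_scan(signal$values, as.integer(min_baseline), k_sigma)
}

#' Detect the start of the post-bolus plateau
#'
#' Runs the same moving-mean vs cumulative-mean divergence rule as
#' [detect_baseline_end()] but starting from the last time point: the values
#' are reversed, the baseline-end detector applied, and the result mapped
#' back, so `detect_postbolus_start(s) == n - detect_baseline_end(rev(s)) + 1`
#' exactly.
#'
#' @inheritParams detect_baseline_end
#' @return 1-based index of the first post-bolus dynamic.
#' @export
detect_postbolus_start <- function(signal, min_baseline = 5L, k_sigma = 2.5) {
  signal <- as_signal(signal)
  n <- length(signal$values)
  b_rev <- divergence_scan(rev(signal$values), as.integer(min_baseline), k_sigma)
  n - b_rev + 1L
}

#' Segment a signal-time course into baseline, first pass and post-bolus
#'
#' The first pass is the region strictly between the end of the baseline and
#' the start of the post-bolus plateau; both plateau endpoints are excluded.
#'
#' @inheritParams detect_baseline_end
#' @return an object of class `first_pass_segmentation` with fields
#'   `baseline_end` (b), `postbolus_start` (p), `first_pass` (indices
#'   `(b+1):(p-1)`) and `n`.
#' @export
segment_first_pass <- function(signal, min_baseline = 5L, k_sigma = 2.5) {
  signal <- as_signal(signal)
  b <- detect_baseline_end(signal, min_baseline, k_sigma)
  p <- detect_postbolus_start(signal, min_baseline, k_sigma)
  if (p - b <= 3L)
    qc_abort(sprintf("degenerate first pass (b = %d, p = %d)", b, p),
             "dscqc_degenerate_first_pass")
  structure(
    list(baseline_end = b, postbolus_start = p,
         first_pass = (b + 1L):(p - 1L), n = length(signal$values)),
    class = "first_pass_segmentation"
  )
}

#' @export
print.first_pass_segmentation <- function(x, ...) {
  cat(sprintf("<first pass: dynamics %d..%d (baseline 1..%d, post-bolus %d..%d)>\n",
              x$baseline_end + 1L, x$postbolus_start - 1L,
              x$baseline_end, x$postbolus_start, x$n))
  invisible(x)
}
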