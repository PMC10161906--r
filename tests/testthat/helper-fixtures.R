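# Shared fixtures, all built in code.

# The worked boxcar-ish course used throughout the boundary/measure examples:
# baseline 100 x5, dip 90/70/60/70/90, post-bolus 100 x5.
example_course <- function(tr = 1, offset = 0, scale = 1) {
  signal_timecourse(scale * c(rep(100, 5), 90, 70, 60, 70, 90, rep(100, 5)) + offset, tr)
}

# Same dip but with a noisy baseline of SD exactly 1 (sample SD).
noisy_baseline_course <- function(tr = 1) {
  signal_timecourse(c(101, 99, 101, 99, 100, 90, 70, 60, 70, 90, rep(100, 5)), tr)
}

# Gaussian feature clouds separated along the SDNR axis: the separable
# cohort for classifier sanity checks (separation in SD units).
gaussian_feature_table <- function(n, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  data.frame(sdnr = stats::rnorm(n) + sep * y,
             rmse_norm = stats::rnorm(n),
             fwhm_s = stats::rnorm(n),
             psr_pct = stats::rnorm(n),
             qr_label = y)
}

# Brute-force pairwise AUC oracle: P(s+ > s-) + 0.5 P(tie).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive crossing-threshold oracle: returns minimal |sens - spec| over
# all observed candidate thresholds.
crossing_oracle_gap <- function(values, labels, orientation) {
  best <- Inf
  for (th in sort(unique(values))) {
    pass <- if (orientation == "higher_is_better") values >= th else values <= th
    sens <- sum(pass & labels == 1) / sum(labels == 1)
    spec <- sum(!pass & labels == 0) / sum(labels == 0)
    best <- min(best, abs(sens - spec))
  }
  best
}
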