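#' Parameters of one synthetic DSC-MRI signal-time course
#'
#' The noiseless course is
#' `s*(t) = s0 - depth * g(t - t0) - R * G(t - t0)`, where `g` is the
#' gamma-variate `t^alpha exp(-t/beta)` normalised to peak 1, `G` its running
#' integral normalised to plateau 1, and `R = depth * (1 - psr_true / 100)`
#' sets the post-bolus plateau (negative `R`, i.e. `psr_true > 100`, yields
#' overshoot / T1-contamination morphology). The integral-shaped step gives a
#' smooth post-bolus plateau rather than an unphysical boxcar. Gaussian noise
#' of SD `sigma` is added, then any artifact applied; truth values are
#' computed from the noiseless curve.
#'
#' @param s0 baseline signal level (> 0).
#' @param sigma baseline noise SD in signal units (>= 0).
#' @param t0 bolus arrival time in seconds (must allow >= 5 baseline
#'   dynamics).
#' @param alpha,beta gamma-variate shape (dimensionless) and decay scale (s).
#' @param depth true peak signal drop in signal units (>= 0).
#' @param psr_true true percentage signal recovery in `[0, 200]`.
#' @param n_dynamics number of dynamics.
#' @param tr_seconds repetition time in seconds.
#' @param artifact optional artifact description, one of
#'   `artifact_spikes(count, amplitude)`, `artifact_first_pass_noise(extra_sd)`,
#'   `artifact_narrow(beta_scale)`, `artifact_shallow(depth_scale)`.
#' @return an object of class `course_params`.
#' @export
course_params <- function(s0 = 1000, sigma = 20, t0 = 20, alpha = 2,
                          beta = 3, depth = 300, psr_true = 85,
                          n_dynamics = 60L, tr_seconds = 2,
                          artifact = NULL) {
  if (s0 <= 0 || sigma < 0 || depth < 0 || psr_true < 0 || psr_true > 200 ||
      tr_seconds <= 0 || alpha <= 0 || beta <= 0 || n_dynamics < 12L ||
      t0 < 5 * tr_seconds)
    qc_abort("invalid params", "dscqc_invalid_params")
  structure(list(s0 = s0, sigma = sigma, t0 = t0, alpha = alpha, beta = beta,
                 depth = depth, psr_true = psr_true,
                 n_dynamics = as.integer(n_dynamics),
                 tr_seconds = tr_seconds, artifact = artifact),
            class = "course_params")
}

#' @rdname course_params
#' @param count,amplitude number of motion spikes and their amplitude in
#'   signal units: spikes replace random non-baseline dynamics with
#'   `s0 +/- amplitude`.
#' @export
artifact_spikes <- function(count = 2L, amplitude = 300) {
  list(type = "spikes", count = as.integer(count), amplitude = amplitude)
}

#' @rdname course_params
#' @param extra_sd extra Gaussian noise SD added inside the first pass only.
#' @export
artifact_first_pass_noise <- function(extra_sd = 75) {
  list(type = "first_pass_noise", extra_sd = extra_sd)
}

#' @rdname course_params
#' @param beta_scale multiplier (< 1) applied to `beta`, narrowing the bolus.
#' @export
artifact_narrow <- function(beta_scale = 0.25) {
  list(type = "narrow", beta_scale = beta_scale)
}

#' @rdname course_params
#' @param depth_scale multiplier (< 1) applied to `depth`, shrinking the drop.
#' @export
artifact_shallow <- function(depth_scale = 0.2) {
  list(type = "shallow", depth_scale = depth_scale)
}

# gamma-variate normalised to peak 1 at u = alpha * beta
gamma_peak1 <- function(u, alpha, beta) {
  out <- numeric(length(u))
  pos <- u > 0
  up <- u[pos] / (alpha * beta)
  out[pos] <- exp(alpha * log(up) + alpha - u[pos] / beta)
  out
}

noiseless_course <- function(p, t) {
  u <- t - p$t0
  R <- p$depth * (1 - p$psr_true / 100)
  p$s0 - p$depth * gamma_peak1(u, p$alpha, p$beta) -
    R * stats::pgamma(pmax(u, 0), shape = p$alpha + 1, scale = p$beta)
}

# Truth values from a finely sampled noiseless curve: FWHM at half the peak
# drop with linear interpolation, matching the measurement's definition.
course_truth <- function(p) {
  tmax <- (p$n_dynamics - 1L) * p$tr_seconds
  t <- seq(0, tmax, by = min(p$tr_seconds, 1) / 50)
  s <- noiseless_course(p, t)
  imin <- which.min(s)
  half <- p$s0 - (p$s0 - s[imin]) / 2
  left <- right <- NA_real_
  if (imin > 1L) for (j in (imin - 1L):1L) {
    if (s[j] >= half && s[j + 1L] < half) {
      left <- t[j] + (s[j] - half) / (s[j] - s[j + 1L]) * (t[j + 1L] - t[j])
      break
    }
  }
  if (imin < length(s)) {
    for (j in imin:(length(s) - 1L)) {
      if (s[j] < half && s[j + 1L] >= half) {
        right <- t[j] + (half - s[j]) / (s[j + 1L] - s[j]) * (t[j + 1L] - t[j])
        break
      }
    }
  }
  list(sdnr_true = if (p$sigma > 0) p$depth / p$sigma else Inf,
       fwhm_true = right - left, psr_true = p$psr_true)
}

#' Simulate one signal-time course
#'
#' @param params a [course_params()]. `narrow` and `shallow` artifacts modify
#'   the generating curve (and hence the truth values); `spikes` and
#'   `first_pass_noise` corrupt the sampled signal after noise, leaving the
#'   truths untouched.
#' @param seed integer seed; same params + same seed gives an identical
#'   signal.
#' @return a list with `signal` (a [signal_timecourse]) and `truth`
#'   (`sdnr_true`, `fwhm_true` in seconds, `psr_true` in percent).
#' @export
simulate_timecourse <- function(params, seed = 1L) {
  stopifnot(inherits(params, "course_params"))
  p <- params
  art <- p$artifact
  if (!is.null(art)) {
    if (art$type == "narrow") p$beta <- p$beta * art$beta_scale
    if (art$type == "shallow") p$depth <- p$depth * art$depth_scale
  }
  rng <- local_rng(seed)
  t <- (seq_len(p$n_dynamics) - 1L) * p$tr_seconds
  s_star <- noiseless_course(p, t)
  values <- s_star + if (p$sigma > 0) rng$rnorm(p$n_dynamics, 0, p$sigma) else 0

  if (!is.null(art)) {
    if (art$type == "first_pass_noise") {
      g <- gamma_peak1(t - p$t0, p$alpha, p$beta)
      fp <- which(g > 0.01)
      if (length(fp))
        values[fp] <- values[fp] + rng$rnorm(length(fp), 0, art$extra_sd)
    } else if (art$type == "spikes") {
      nonbase <- which(t > p$t0)
      k <- min(art$count, length(nonbase))
      if (k > 0L) {
        idx <- nonbase[rng$sample_int(length(nonbase), k)]
        sign <- ifelse(rng$runif(k) < 0.5, -1, 1)
        values[idx] <- p$s0 + sign * art$amplitude
      }
    }
  }
  list(signal = signal_timecourse(values, p$tr_seconds),
       truth = c(course_truth(p),
                 list(artifact = if (is.null(art)) "none" else art$type)))
}

#' Cohort description for the synthetic generator
#'
#' Defaults emulate a multi-protocol paediatric cohort: TR uniform over
#' 1.3-4.9 s, baseline length 8-14 dynamics, true SDNR log-normal around 16,
#' gamma-variate widths giving first-pass FWHM of roughly 4-14 s, PSR normal
#' around 85% (truncated to `[0, 200]`), and a 10% prevalence for each of the
#' four artifact classes (mutually exclusive; 60% of courses clean). The
#' quality label is derived from the truth values by `rule`: pass iff true
#' SDNR >= `rule$sdnr_min`, true FWHM inside `rule$fwhm_range` and true PSR
#' inside `rule$psr_range` (components may be omitted to drop them from the
#' rule). These prevalences and distributions are package choices, not
#' published values.
#'
#' @param tr_range TR sampling range in seconds.
#' @param n_dynamics dynamics per course.
#' @param s0 baseline level.
#' @param depth_frac true peak drop as a fraction of `s0`.
#' @param sdnr_sampler `"lognormal"` (meanlog/sdlog), `"uniform"` (lim), or
#'   `"gap_uniform"` (uniform over `lim` with the interval `sdnr_gap` cut
#'   out, giving two well-separated classes around a label boundary).
#' @param sdnr_meanlog,sdnr_sdlog,sdnr_lim,sdnr_gap true-SDNR distribution
#'   parameters.
#' @param alpha_range,beta_range gamma-variate shape ranges.
#' @param psr_mean,psr_sd true-PSR distribution (truncated to `[0, 200]`).
#' @param baseline_dynamics integer range for the number of baseline
#'   dynamics (bolus arrival `t0 = n_baseline * TR`).
#' @param artifact_probs named probabilities for `none`, `spikes`,
#'   `first_pass_noise`, `narrow`, `shallow`; must sum to 1.
#' @param rule truth labelling rule (see above).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(tr_range = c(1.3, 4.9), n_dynamics = 60L, s0 = 1000,
                        depth_frac = 0.3,
                        sdnr_sampler = c("lognormal", "uniform", "gap_uniform"),
                        sdnr_meanlog = log(16), sdnr_sdlog = 0.5,
                        sdnr_lim = c(3, 13), sdnr_gap = c(6.5, 9.5),
                        alpha_range = c(1.5, 2.5), beta_range = c(2.5, 4.5),
                        psr_mean = 85, psr_sd = 20,
                        baseline_dynamics = c(8L, 14L),
                        artifact_probs = c(none = 0.6, spikes = 0.1,
                                           first_pass_noise = 0.1,
                                           narrow = 0.1, shallow = 0.1),
                        rule = list(sdnr_min = 7.6, fwhm_range = c(3, 19),
                                    psr_range = c(42.9, 130.4))) {
  sdnr_sampler <- match.arg(sdnr_sampler)
  stopifnot(abs(sum(artifact_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Cohort description for SDNR-threshold recovery experiments
#'
#' A single-protocol world built for threshold-calibration validation: TR
#' near 2 s, long stable baselines (45-55 dynamics, so the baseline-SD
#' estimate is tight), gradual gamma-variate boluses, full signal recovery,
#' no artifacts, and true SDNR uniform on `[3, 13]` except for a small buffer
#' `(7.4, 8.6)` around the label boundary, which separates the classes
#' labelled by the rule "true SDNR >= 8". Extract features from it with
#' `min_baseline = 15, k_sigma = 1.5` (see the vignette for why the default
#' `k_sigma = 2.5` biases SDNR low on gradual-onset boluses).
#'
#' @return a [cohort_spec()].
#' @export
cohort_spec_sdnr_recovery <- function() {
  cohort_spec(tr_range = c(1.8, 2.2), n_dynamics = 110L,
              sdnr_sampler = "gap_uniform", sdnr_lim = c(3, 13),
              sdnr_gap = c(7.4, 8.6),
              alpha_range = c(0.8, 1.2), beta_range = c(5, 7),
              psr_mean = 100, psr_sd = 5,
              baseline_dynamics = c(45L, 55L),
              artifact_probs = c(none = 1, spikes = 0, first_pass_noise = 0,
                                 narrow = 0, shallow = 0),
              rule = list(sdnr_min = 8))
}

truth_label <- function(truth, rule) {
  pass <- TRUE
  if (!is.null(rule$sdnr_min)) pass <- pass && truth$sdnr_true >= rule$sdnr_min
  if (!is.null(rule$fwhm_range))
    pass <- pass && is.finite(truth$fwhm_true) &&
      truth$fwhm_true >= rule$fwhm_range[1L] && truth$fwhm_true <= rule$fwhm_range[2L]
  if (!is.null(rule$psr_range))
    pass <- pass && truth$psr_true >= rule$psr_range[1L] &&
      truth$psr_true <= rule$psr_range[2L]
  as.integer(pass)
}

#' Simulate a labelled cohort of signal-time courses
#'
#' Draws per-course parameters from the cohort description, simulates each
#' course, and assigns the quality label from the truth values via the
#' cohort's rule. Re-deriving labels from the returned truth table and rule
#' reproduces them exactly.
#'
#' @param n number of courses (>= 20).
#' @param seed integer seed; all per-course seeds derive from it.
#' @param spec a [cohort_spec()].
#' @return a list (class `dsc_cohort`) with `signals` (list of
#'   [signal_timecourse]), `truth` (`data.frame`: `course`, `tr_seconds`,
#'   `sdnr_true`, `fwhm_true`, `psr_true`, `artifact`, `qr_label`) and
#'   `spec`.
#' @export
simulate_cohort <- function(n, seed = 1L, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n < 20L) qc_abort("cohort too small (need n >= 20)", "dscqc_invalid_params")
  rng <- local_rng(seed)
  tr <- rng$runif(n, spec$tr_range[1L], spec$tr_range[2L])
  nb <- spec$baseline_dynamics[1L] +
    rng$sample_int(spec$baseline_dynamics[2L] - spec$baseline_dynamics[1L] + 1L,
                   n, replace = TRUE) - 1L
  sdnr_true <- switch(spec$sdnr_sampler,
    lognormal = exp(rng$rnorm(n, spec$sdnr_meanlog, spec$sdnr_sdlog)),
    uniform = rng$runif(n, spec$sdnr_lim[1L], spec$sdnr_lim[2L]),
    gap_uniform = {
      # uniform over lim with the gap removed
      u <- rng$runif(n, 0, 1)
      lo_len <- spec$sdnr_gap[1L] - spec$sdnr_lim[1L]
      hi_len <- spec$sdnr_lim[2L] - spec$sdnr_gap[2L]
      frac <- lo_len / (lo_len + hi_len)
      ifelse(u < frac,
             spec$sdnr_lim[1L] + u / frac * lo_len,
             spec$sdnr_gap[2L] + (u - frac) / (1 - frac) * hi_len)
    })
  alpha <- rng$runif(n, spec$alpha_range[1L], spec$alpha_range[2L])
  beta <- rng$runif(n, spec$beta_range[1L], spec$beta_range[2L])
  psr <- pmin(pmax(rng$rnorm(n, spec$psr_mean, spec$psr_sd), 0), 200)
  art_names <- names(spec$artifact_probs)
  art_draw <- rng$runif(n)
  cum <- cumsum(spec$artifact_probs)
  art <- art_names[vapply(art_draw, function(u) which(u <= cum)[1L], integer(1L))]
  course_seeds <- derive_seeds(rng$next_seed(), n)

  depth <- spec$depth_frac * spec$s0
  signals <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    artifact <- switch(art[i], none = NULL,
                       spikes = artifact_spikes(),
                       first_pass_noise = artifact_first_pass_noise(extra_sd = depth / 4),
                       narrow = artifact_narrow(),
                       shallow = artifact_shallow())
    p <- course_params(s0 = spec$s0, sigma = depth / sdnr_true[i],
                       t0 = nb[i] * tr[i], alpha = alpha[i], beta = beta[i],
                       depth = depth, psr_true = psr[i],
                       n_dynamics = spec$n_dynamics, tr_seconds = tr[i],
                       artifact = artifact)
    sim <- simulate_timecourse(p, course_seeds[i])
    sim$signal$voxel_id <- i
    signals[[i]] <- sim$signal
    truth[[i]] <- data.frame(course = i, tr_seconds = tr[i],
                             sdnr_true = sim$truth$sdnr_true,
                             fwhm_true = sim$truth$fwhm_true,
                             psr_true = sim$truth$psr_true,
                             artifact = sim$truth$artifact,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth$qr_label <- vapply(seq_len(n), function(i)
    truth_label(as.list(truth[i, ]), spec$rule), integer(1L))
  structure(list(signals = signals, truth = truth, spec = spec),
            class = "dsc_cohort")
}

#' Labelled feature table from a synthetic cohort
#'
#' Convenience wrapper: extracts the quality measures from every simulated
#' course and joins the truth labels, yielding the input expected by
#' [calibrate_kfold()] and [train_classifier()].
#'
#' @param cohort a `dsc_cohort` from [simulate_cohort()].
#' @inheritParams extract_features
#' @return the feature table with an extra `qr_label` column.
#' @export
cohort_feature_table <- function(cohort, min_baseline = 5L, k_sigma = 2.5) {
  stopifnot(inherits(cohort, "dsc_cohort"))
  ft <- feature_table(cohort$signals, min_baseline, k_sigma)
  ft$qr_label <- cohort$truth$qr_label
  ft
}

#' Write a synthetic 4D phantom as NIfTI
#'
#' Builds an `nx x ny x nz x n_dynamics` volume whose interior voxels hold
#' simulated courses with smoothly varying parameters (true peak drop rises
#' along x from 100 to 600 signal units, so with `sigma = 30` the true SDNR
#' spans roughly 3-20; true PSR rises along y from 20 to 160%) and whose
#' one-voxel
#' border is zero-signal "out of brain" background. A 3D truth map (1 pass,
#' 0 fail, NaN border) labelled by the cohort rule accompanies the volume.
#'
#' @param grid integer triple `(nx, ny, nz)`, each spatial plane at least
#'   4 x 4.
#' @param n_dynamics dynamics per voxel.
#' @param tr_seconds repetition time (s).
#' @param sigma noise SD (0 for a noiseless phantom).
#' @param seed integer seed.
#' @param path output path for the 4D NIfTI volume.
#' @param truth_path optional output path for the 3D truth-map NIfTI.
#' @param rule truth labelling rule (see [cohort_spec()]); the default drops
#'   the SDNR component because a noiseless phantom has no baseline noise.
#' @return invisibly, a list with `path`, `truth_path`, the truth label
#'   array, and the per-voxel true parameter arrays.
#' @export
write_phantom <- function(grid = c(8L, 8L, 1L), n_dynamics = 40L,
                          tr_seconds = 1.5, sigma = 0, seed = 1L,
                          path, truth_path = NULL,
                          rule = list(psr_range = c(42.9, 130.4))) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || grid[1L] < 4L || grid[2L] < 4L || grid[3L] < 1L)
    qc_abort("grid must be at least 4 x 4 x 1", "dscqc_invalid_params")
  nx <- grid[1L]; ny <- grid[2L]; nz <- grid[3L]
  vol <- array(0, dim = c(nx, ny, nz, n_dynamics))
  labels <- array(NA_real_, dim = c(nx, ny, nz))
  sdnr_map <- psr_map <- fwhm_map <- array(NA_real_, dim = c(nx, ny, nz))
  seeds <- derive_seeds(seed, nx * ny * nz)
  interior_x <- 2:(nx - 1L); interior_y <- 2:(ny - 1L)
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (!(x %in% interior_x && y %in% interior_y)) next
    # depth rises along x so that, for sigma > 0, true SDNR spans ~2-20
    depth <- 100 + (600 - 100) * (x - 2) / max(nx - 3, 1)
    psr_t <- 20 + (160 - 20) * (y - 2) / max(ny - 3, 1)
    p <- course_params(s0 = 1000, sigma = sigma,
                       t0 = 8 * tr_seconds, alpha = 2, beta = 3,
                       depth = depth, psr_true = psr_t,
                       n_dynamics = n_dynamics, tr_seconds = tr_seconds)
    sim <- simulate_timecourse(p, seeds[(z - 1L) * nx * ny + (y - 1L) * nx + x])
    vol[x, y, z, ] <- sim$signal$values
    sdnr_map[x, y, z] <- sim$truth$sdnr_true
    psr_map[x, y, z] <- sim$truth$psr_true
    fwhm_map[x, y, z] <- sim$truth$fwhm_true
    labels[x, y, z] <- truth_label(sim$truth, rule)
  }
  write_nifti(vol, path, pixdim = c(1, 1, 1), tr_seconds = tr_seconds)
  if (!is.null(truth_path)) write_nifti(labels, truth_path, pixdim = c(1, 1, 1))
  invisible(list(path = path, truth_path = truth_path, labels = labels,
                 sdnr_true = sdnr_map, psr_true = psr_map,
                 fwhm_true = fwhm_map))
}
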