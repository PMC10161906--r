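#' Quantitative quality measures for DSC-MRI signal-time courses
#'
#' Four measures summarise how usable a bolus-passage signal-time course is:
#' the signal drop-to-noise ratio (SDNR), the gamma-variate fit RMSE
#' normalised to the first-pass area, the full width at half maximum (FWHM)
#' of the first pass in seconds, and the percentage signal recovery (PSR).
#'
#' @name quality-measures
NULL

baseline_mean <- function(signal, seg) mean(signal$values[seq_len(seg$baseline_end)])

# Index of the first-pass minimum, earliest on ties.
first_pass_min_index <- function(signal, seg) {
  fp <- seg$first_pass
  fp[which.min(signal$values[fp])]
}

#' Signal drop
#'
#' Difference between the mean baseline signal and the mean of the first-pass
#' minimum and its two adjacent dynamics. The adjacent dynamics are taken from
#' the full series even when they fall outside the first pass.
#'
#' @param signal a [signal_timecourse].
#' @param seg a `first_pass_segmentation` from [segment_first_pass()].
#' @return signal drop in signal units.
#' @export
signal_drop <- function(signal, seg) {
  signal <- as_signal(signal)
  m <- first_pass_min_index(signal, seg)
  if (m <= 1L || m >= length(signal$values))
    qc_abort("minimum at series boundary", "dscqc_min_at_boundary")
  baseline_mean(signal, seg) - mean(signal$values[(m - 1L):(m + 1L)])
}

#' Signal drop-to-noise ratio (SDNR)
#'
#' Signal drop divided by the sample standard deviation of the baseline
#' dynamics. Dimensionless; invariant under affine intensity transforms.
#'
#' @inheritParams signal_drop
#' @return SDNR (dimensionless).
#' @export
sdnr <- function(signal, seg) {
  signal <- as_signal(signal)
  s <- stats::sd(signal$values[seq_len(seg$baseline_end)])
  if (s == 0)
    qc_abort("degenerate baseline (zero standard deviation)", "dscqc_degenerate_baseline")
  signal_drop(signal, seg) / s
}

# Gamma-variate model of the first-pass dip: y(t) = c - K t^alpha e^(-t/beta),
# t in seconds from the end of the baseline. Evaluated in log space for
# numerical stability at large alpha.
gamma_variate_dip <- function(t, K, alpha, beta) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- K * exp(alpha * log(t[pos]) - t[pos] / beta)
  out
}

#' Fit a gamma-variate to the first pass
#'
#' Nonlinear least squares of `y(t) = c - K t^alpha exp(-t / beta)` over the
#' first-pass dynamics, with `t = (index - b) * TR` seconds and `c` fixed at
#' the mean baseline signal (only K, alpha, beta are free). The fit RMSE is
#' normalised to the area of the first pass; by default the trapezoidal area
#' of the drop curve (baseline mean minus signal) in signal-seconds, which
#' makes the normalised RMSE affine-invariant. Non-convergence is not an
#' error: the fit is flagged and the normalised RMSE set to the sentinel 1.0.
#'
#' @inheritParams signal_drop
#' @param normalisation `"drop_area"` (default) divides the RMSE by the
#'   trapezoidal area of `baseline mean - signal` over the first pass;
#'   `"raw_area"` divides by the trapezoidal area under the raw signal.
#' @return an object of class `gamma_fit`: fields `c` (fixed baseline level),
#'   `K`, `alpha`, `beta` (seconds), `rmse` (signal units), `rmse_norm`
#'   (1/seconds), `converged`, `t` and `fitted`.
#' @export
fit_gamma_variate <- function(signal, seg,
                              normalisation = c("drop_area", "raw_area")) {
  signal <- as_signal(signal)
  normalisation <- match.arg(normalisation)
  fp <- seg$first_pass
  if (length(fp) < 4L)
    qc_abort("first pass too short for a 3-parameter fit", "dscqc_first_pass_too_short")
  tr <- signal$tr_seconds
  t <- (fp - seg$baseline_end) * tr
  cbase <- baseline_mean(signal, seg)
  drop <- cbase - signal$values[fp]          # observed dip, >= 0 for clean data

  area <- if (normalisation == "drop_area") {
    trapz(t, drop)
  } else {
    trapz(t, signal$values[fp])
  }

  dur <- max(t)
  # fit on the unit-scaled drop curve so the optimiser (and hence the
  # convergence flag) is invariant under intensity scaling; K rescales back
  scale <- max(abs(drop), .Machine$double.eps)
  drop_s <- drop / scale
  lower <- c(K = 0, alpha = 1e-6, beta = 0.1)
  upper <- c(K = Inf, alpha = 10, beta = 100)
  sse <- function(par) {
    r <- drop_s - gamma_variate_dip(t, par[1L], par[2L], par[3L])
    sum(r * r)
  }
  # K0 matches the observed peak dip at the gamma-variate's own peak given
  # (alpha0, beta0); several starts guard against the shallow K/alpha ridge.
  starts <- list(c(alpha = 1.5, beta = dur / 4),
                 c(alpha = 0.8, beta = dur / 2),
                 c(alpha = 3.0, beta = dur / 8))
  run_opt <- function(par0) {
    fit <- tryCatch(
      stats::optim(par0, sse, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL
    )
    # L-BFGS-B occasionally reports an abnormal linesearch right at the
    # optimum; one restart from the returned point settles the flag
    if (!is.null(fit) && fit$convergence != 0L) {
      fit2 <- tryCatch(
        stats::optim(fit$par, sse, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 500L, factr = 1e4)),
        error = function(e) NULL
      )
      if (!is.null(fit2) && fit2$value <= fit$value) fit <- fit2
    }
    fit
  }
  best <- NULL
  for (st in starts) {
    a0 <- st[["alpha"]]; b0 <- min(max(st[["beta"]], 0.1), 100)
    tm <- t[which.max(drop_s)]
    denom <- gamma_variate_dip(tm, 1, a0, b0)
    k0 <- if (denom > 0) max(max(drop_s), 0) / denom else 1
    fit <- run_opt(c(k0, a0, b0))
    if (is.null(fit) || !is.finite(fit$value)) next
    # prefer converged fits; among equals, the lowest objective
    better <- is.null(best) ||
      (fit$convergence == 0L && best$convergence != 0L) ||
      ((fit$convergence == 0L) == (best$convergence == 0L) &&
       fit$value < best$value)
    if (better) best <- fit
  }

  converged <- !is.null(best) && best$convergence == 0L && is.finite(best$value)
  if (converged) {
    par <- best$par
    par[1L] <- par[1L] * scale
    fitted_drop <- gamma_variate_dip(t, par[1L], par[2L], par[3L])
    rmse <- sqrt(best$value / length(t)) * scale
    rmse_norm <- if (area > 0) rmse / area else 1.0
  } else {
    par <- c(NA_real_, NA_real_, NA_real_)
    fitted_drop <- rep(NA_real_, length(t))
    rmse <- NA_real_
    rmse_norm <- 1.0
  }
  structure(
    list(c = cbase, K = par[1L], alpha = par[2L], beta = par[3L],
         rmse = rmse, rmse_norm = rmse_norm, converged = converged,
         t = t, fitted = cbase - fitted_drop, normalisation = normalisation),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<gamma_fit: c = %.4g, K = %.4g, alpha = %.4g, beta = %.4g s, rmse_norm = %.4g /s>\n",
                x$c, x$K, x$alpha, x$beta, x$rmse_norm))
  } else {
    cat("<gamma_fit: did not converge (rmse_norm sentinel 1.0)>\n")
  }
  invisible(x)
}

# Trapezoidal area under y(x) on an increasing grid.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L))) / 2

#' Full width at half maximum of the first pass
#'
#' Width of the first pass, in seconds, at half the signal drop. The half
#' level is `baseline mean - signal_drop / 2` (signal drop uses the 3-point
#' minimum mean). From the first-pass minimum the series is searched outward
#' in both directions for the nearest adjacent-dynamic pair bracketing the
#' half level; each crossing is located by linear interpolation in dynamic
#' units and the width converted to seconds via TR.
#'
#' @inheritParams signal_drop
#' @return FWHM in seconds.
#' @export
fwhm <- function(signal, seg) {
  signal <- as_signal(signal)
  v <- signal$values
  n <- length(v)
  drop <- signal_drop(signal, seg)
  if (drop <= 0)
    qc_abort("non-positive signal drop", "dscqc_zero_drop")
  half <- baseline_mean(signal, seg) - drop / 2
  m <- first_pass_min_index(signal, seg)

  t_left <- NA_real_
  for (j in (m - 1L):1L) {
    if (j < 1L) break
    if (v[j] >= half && v[j + 1L] < half) {
      t_left <- j + (v[j] - half) / (v[j] - v[j + 1L])
      break
    }
  }
  t_right <- NA_real_
  if (m <= n - 1L) {
    for (j in m:(n - 1L)) {
      if (v[j] < half && v[j + 1L] >= half) {
        t_right <- j + (half - v[j]) / (v[j + 1L] - v[j])
        break
      }
    }
  }
  if (!is.finite(t_left) || !is.finite(t_right))
    qc_abort("no half-level crossing before series boundary", "dscqc_no_half_crossing")
  (t_right - t_left) * signal$tr_seconds
}

#' Percentage signal recovery (PSR)
#'
#' T2*-recovery (mean post-bolus signal minus the 3-point first-pass minimum
#' mean) as a percentage of the signal drop. Values above 100% indicate
#' post-bolus overshoot (T1-contamination morphology); values well below
#' 100% indicate residual susceptibility effects.
#'
#' @inheritParams signal_drop
#' @return PSR in percent.
#' @export
psr <- function(signal, seg) {
  signal <- as_signal(signal)
  drop <- signal_drop(signal, seg)
  if (drop == 0)
    qc_abort("zero signal drop", "dscqc_zero_drop")
  v <- signal$values
  m <- first_pass_min_index(signal, seg)
  post <- mean(v[seg$postbolus_start:length(v)])
  100 * (post - mean(v[(m - 1L):(m + 1L)])) / drop
}

feature_columns <- c("voxel_id", "i", "j", "k", "baseline_end",
                     "postbolus_start", "sdnr", "rmse_norm", "fwhm_s",
                     "psr_pct", "fit_converged", "valid", "reason")

voxel_id_fields <- function(voxel_id) {
  if (is.null(voxel_id))
    return(list(voxel_id = NA_character_, i = NA_integer_, j = NA_integer_, k = NA_integer_))
  if (length(voxel_id) == 3L) {
    v <- as.integer(voxel_id)
    list(voxel_id = paste(v, collapse = "_"), i = v[1L], j = v[2L], k = v[3L])
  } else {
    list(voxel_id = as.character(voxel_id[1L]),
         i = NA_integer_, j = NA_integer_, k = NA_integer_)
  }
}

invalid_feature_row <- function(voxel_id, reason) {
  id <- voxel_id_fields(voxel_id)
  data.frame(voxel_id = id$voxel_id, i = id$i, j = id$j, k = id$k,
             baseline_end = NA_integer_, postbolus_start = NA_integer_,
             sdnr = NA_real_, rmse_norm = NA_real_, fwhm_s = NA_real_,
             psr_pct = NA_real_, fit_converged = NA, valid = FALSE,
             reason = reason, stringsAsFactors = FALSE)
}

#' Extract all four quality measures from one signal-time course
#'
#' Runs [segment_first_pass()] and then the four measures. Per-measure
#' failures (e.g. a degenerate baseline for SDNR) become `NA` values in the
#' returned row, not errors, so a feature table can always be assembled;
#' only an unrecoverable segmentation failure marks the whole voxel invalid.
#'
#' @inheritParams detect_baseline_end
#' @param normalisation passed to [fit_gamma_variate()].
#' @return a one-row `data.frame` with columns `voxel_id, i, j, k,
#'   baseline_end, postbolus_start, sdnr, rmse_norm, fwhm_s, psr_pct,
#'   fit_converged, valid, reason`.
#' @export
extract_features <- function(signal, min_baseline = 5L, k_sigma = 2.5,
                             normalisation = "drop_area") {
  signal <- as_signal(signal)
  seg <- tryCatch(segment_first_pass(signal, min_baseline, k_sigma),
                  dscqc_error = function(e) e)
  if (inherits(seg, "condition"))
    return(invalid_feature_row(signal$voxel_id, qc_reason(seg)))

  reasons <- character(0)
  meas <- function(expr) {
    tryCatch(expr, dscqc_error = function(e) {
      reasons <<- c(reasons, qc_reason(e))
      NA_real_
    })
  }
  sdnr_v <- meas(sdnr(signal, seg))
  fwhm_v <- meas(fwhm(signal, seg))
  psr_v <- meas(psr(signal, seg))
  fit <- tryCatch(fit_gamma_variate(signal, seg, normalisation),
                  dscqc_error = function(e) {
                    reasons <<- c(reasons, qc_reason(e))
                    NULL
                  })
  id <- voxel_id_fields(signal$voxel_id)
  data.frame(voxel_id = id$voxel_id, i = id$i, j = id$j, k = id$k,
             baseline_end = seg$baseline_end,
             postbolus_start = seg$postbolus_start,
             sdnr = sdnr_v,
             rmse_norm = if (is.null(fit)) NA_real_ else fit$rmse_norm,
             fwhm_s = fwhm_v, psr_pct = psr_v,
             fit_converged = if (is.null(fit)) NA else fit$converged,
             valid = TRUE,
             reason = if (length(reasons)) paste(unique(reasons), collapse = ";") else "",
             stringsAsFactors = FALSE)
}

#' Build a feature table from many signal-time courses
#'
#' Order-preserving: one row per input course, invalid courses flagged with a
#' reason rather than dropped.
#'
#' @param signals a list of [signal_timecourse] objects.
#' @inheritParams extract_features
#' @return a `data.frame`, one row per course (see [extract_features()]).
#' @export
feature_table <- function(signals, min_baseline = 5L, k_sigma = 2.5,
                          normalisation = "drop_area") {
  stopifnot(is.list(signals))
  if (length(signals) == 0L)
    return(invalid_feature_row(NULL, "empty")[0L, ])
  rows <- lapply(seq_along(signals), function(i) {
    s <- signals[[i]]
    if (is.null(s$voxel_id)) s$voxel_id <- i
    extract_features(s, min_baseline, k_sigma, normalisation)
  })
  do.call(rbind, rows)
}

#' Write a feature table to CSV
#'
#' @param features a feature table from [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
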