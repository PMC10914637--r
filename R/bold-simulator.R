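#' Gamma hemodynamic response kernel
#'
#' Single-gamma HRF with mean lag 3 s and standard deviation 1.5 s, the
#' monkey-calibrated response used for all regressor convolution. Shape and
#' scale follow from moment matching: shape = (mean/SD)^2 = 4,
#' scale = SD^2/mean = 0.75 s. The kernel is sampled on `[0, 30]` s at `dt`
#' and normalized to unit discrete integral, so convolved-regressor
#' amplitudes keep signal units.
#'
#' @param dt Sampling step in seconds, `0 < dt <= 0.1` recommended for
#'   kernel-accuracy work; the analysis grid `tr/10 = 0.148` s is also
#'   accepted.
#' @param mean_lag Kernel mean in seconds.
#' @param sd_lag Kernel SD in seconds.
#' @param t_max Support end in seconds.
#' @return Numeric kernel vector with attributes `dt` and `time`.
#' @export
hrf_kernel <- function(dt = 0.01, mean_lag = 3, sd_lag = 1.5, t_max = 30) {
  if (!is.numeric(dt) || dt <= 0) stop_param("dt must be positive")
  if (mean_lag <= 0 || sd_lag <= 0) stop_param("mean_lag and sd_lag must be positive")
  shape <- (mean_lag / sd_lag)^2
  scale <- sd_lag^2 / mean_lag
  tt <- seq(0, t_max, by = dt)
  k <- stats::dgamma(tt, shape = shape, scale = scale)
  k <- k / (sum(k) * dt)
  attr(k, "dt") <- dt
  attr(k, "time") <- tt
  attr(k, "shape") <- shape
  attr(k, "scale") <- scale
  k
}

#' Discrete moments of a kernel
#'
#' @param k Kernel from [hrf_kernel()].
#' @return `c(mean, sd)` of the normalized discrete kernel, in seconds.
#' @export
kernel_moments <- function(k) {
  tt <- attr(k, "time"); dt <- attr(k, "dt")
  w <- k / sum(k)
  m <- sum(tt * w)
  v <- sum((tt - m)^2 * w)
  c(mean = m, sd = sqrt(v))
}

#' Ground-truth effect sizes for BOLD simulation
#'
#' @param amp_congruent,amp_incongruent Event amplitudes (signal units) for
#'   congruent and incongruent decisions; their difference is the injected
#'   incongruency effect, of either sign.
#' @param amp_rt RT modulation (signal units per z-unit).
#' @param ppi_beta Coupling of a physiological source ROI onto this ROI on
#'   incongruent trials (unitless).
#' @param noise_sd White-noise SD (signal units).
#' @param ar1_phi AR(1) coefficient of the noise, `|phi| < 1`.
#' @param drift_amp Amplitude of the slow cosine drift (signal units).
#' @param baseline Constant baseline.
#' @param confound_mix Weights with which the generated confound columns leak
#'   into the signal.
#' @return An object of class `ground_truth_effects`.
#' @export
ground_truth_effects <- function(amp_congruent = 0.5, amp_incongruent = 1,
                                 amp_rt = 0.2, ppi_beta = 0, noise_sd = 0.5,
                                 ar1_phi = 0.3, drift_amp = 1, baseline = 100,
                                 confound_mix = c(0.2, -0.1, 0.1)) {
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (abs(ar1_phi) >= 1) stop_param("ar1_phi must satisfy |phi| < 1")
  structure(list(amp_congruent = amp_congruent, amp_incongruent = amp_incongruent,
                 amp_rt = amp_rt, ppi_beta = ppi_beta, noise_sd = noise_sd,
                 ar1_phi = ar1_phi, drift_amp = drift_amp, baseline = baseline,
                 confound_mix = confound_mix),
            class = "ground_truth_effects")
}

# boxcar indicator on a fine grid; half-open intervals [onset, onset+dur)
event_boxcar <- function(onsets, durations, amplitudes, n_fine, dt) {
  x <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- ceiling((onsets[i] + durations[i]) / dt)
    if (a > n_fine) next
    b <- min(b, n_fine)
    x[a:b] <- x[a:b] + amplitudes[i]
  }
  x
}

convolve_fine <- function(x, kernel, dt) {
  out <- stats::convolve(x, rev(kernel), type = "open")[seq_along(x)]
  out * dt
}

# TR samples are taken at TR midpoints of the fine grid (dt = tr/10):
# sample i (1-based) lives at fine index (i-1)*10 + 6.
tr_sample_index <- function(n_tr, upsample = 10) {
  (seq_len(n_tr) - 1L) * upsample + upsample %/% 2 + 1L
}

#' Simulate an ROI BOLD time series with known injected effects
#'
#' Builds, on a fine grid (`tr/10`), decision-locked boxcar events whose
#' amplitude depends on trial congruency plus an RT-modulated component,
#' convolves them with the gamma HRF, decimates to the TR grid, and adds a
#' slow cosine drift, AR(1)-plus-white noise, a leak of generated motion-like
#' confounds, and (optionally) a psychophysiological coupling term
#' `ppi_beta * physio * m(t)` where `m(t)` is the convolved
#' incongruent-decision regressor of this schedule.
#'
#' @param schedule Completed trial table for one session (one condition).
#' @param effects [ground_truth_effects()].
#' @param roi ROI label (`"dmFPC"`, `"mSTS"`, `"lateral_mSTS"`, `"AM"`,
#'   `"EVC"`, `"area47_12o"`, `"other"`).
#' @param duration Series duration in seconds; defaults to last outcome +
#'   30 s.
#' @param tr Repetition time in seconds.
#' @param seed Integer seed; the stream is derived from
#'   `(seed, session, roi)`.
#' @param physio Optional `roi_timeseries` used as the physiological source
#'   of the PPI term (must share the TR grid).
#' @param event_duration Decision boxcar length in seconds.
#' @param n_confounds Number of generated confound columns.
#' @return An object of class `roi_timeseries`: list with `values`, `tr`,
#'   `roi_label`, `confounds`, `session_id`, `ground_truth`.
#' @export
simulate_roi_bold <- function(schedule, effects = ground_truth_effects(),
                              roi = "dmFPC", duration = NULL, tr = 1.48,
                              seed = 1, physio = NULL, event_duration = 1,
                              n_confounds = 3) {
  roi <- match.arg(roi, c("dmFPC", "mSTS", "lateral_mSTS", "AM", "EVC",
                          "area47_12o", "other"))
  if (!inherits(effects, "ground_truth_effects")) {
    stop_param("effects must be ground_truth_effects")
  }
  if (is.null(duration)) duration <- max(schedule$onset_outcome) + 30
  if (any(schedule$onset_decision > duration - 30)) {
    stop_param("all event onsets must fall before duration - 30 s")
  }
  n_tr <- floor(duration / tr)
  up <- 10L
  dt <- tr / up
  n_fine <- n_tr * up
  kernel <- hrf_kernel(dt = dt)

  sid <- schedule$session_id[1]
  old <- .Random.seed_guard(derive_seed(seed, sid, roi, "bold"))
  on.exit(old(), add = TRUE)

  amp <- ifelse(schedule$congruent, effects$amp_congruent, effects$amp_incongruent)
  ev <- event_boxcar(schedule$onset_decision, rep(event_duration, nrow(schedule)),
                     amp, n_fine, dt)
  rtz <- zscore(schedule$rt)
  ev_rt <- event_boxcar(schedule$onset_decision, rep(event_duration, nrow(schedule)),
                        effects$amp_rt * rtz, n_fine, dt)
  task_fine <- convolve_fine(ev + ev_rt, kernel, dt)
  idx <- tr_sample_index(n_tr, up)
  signal <- task_fine[idx]

  if (effects$ppi_beta != 0 && !is.null(physio)) {
    incog <- event_boxcar(schedule$onset_decision[!schedule$congruent],
                          rep(event_duration, sum(!schedule$congruent)),
                          rep(1, sum(!schedule$congruent)), n_fine, dt)
    m <- convolve_fine(incog, kernel, dt)[idx]
    pv <- physio$values - mean(physio$values)
    if (length(pv) != n_tr) stop_param("physio series length must match the TR grid")
    signal <- signal + effects$ppi_beta * pv * m
  }

  t_tr <- (seq_len(n_tr) - 0.5) * tr
  drift <- 0
  if (effects$drift_amp > 0) {
    # low-frequency cosines, all slower than the 100 s high-pass cutoff
    periods <- c(300, 480, 720)
    phases <- stats::runif(3, 0, 2 * pi)
    drift <- effects$drift_amp *
      rowSums(sapply(seq_along(periods),
                     function(j) cos(2 * pi * t_tr / periods[j] + phases[j]) / j))
  }

  noise <- 0
  if (effects$noise_sd > 0) {
    # AR(1) driven by white innovations, scaled to marginal SD = noise_sd
    innov_sd <- effects$noise_sd * sqrt(1 - effects$ar1_phi^2)
    noise <- as.numeric(stats::filter(stats::rnorm(n_tr, 0, innov_sd),
                                      effects$ar1_phi, method = "recursive"))
  }

  confounds <- matrix(0, n_tr, n_confounds,
                      dimnames = list(NULL, paste0("confound_", seq_len(n_confounds))))
  if (n_confounds > 0) {
    for (j in seq_len(n_confounds)) {
      rw <- cumsum(stats::rnorm(n_tr))
      sm <- as.numeric(stats::filter(rw, rep(1 / 5, 5), sides = 2))
      sm[is.na(sm)] <- rw[is.na(sm)]
      confounds[, j] <- as.numeric(scale(sm))
    }
    mix <- rep_len(effects$confound_mix, n_confounds)
    signal <- signal + as.numeric(confounds %*% mix)
  }

  values <- effects$baseline + signal + drift + noise
  structure(list(values = values, tr = tr, roi_label = roi,
                 confounds = confounds, session_id = sid,
                 ground_truth = effects),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> roi=%s session=%s n=%d tr=%.3gs confounds=%d\n",
              x$roi_label, x$session_id, length(x$values), x$tr,
              ncol(x$confounds)))
  invisible(x)
}
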