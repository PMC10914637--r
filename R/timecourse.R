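#' Residualize motion and upsample an ROI series
#'
#' Regresses the series on its confound columns plus an intercept and
#' linearly interpolates the residual to 10 samples per TR, the grid on which
#' trial epochs are extracted.
#'
#' @param series A `roi_timeseries`.
#' @param upsample Samples per TR (default 10).
#' @return List with `values` (fine-grid residual), `dt` (`tr/upsample`),
#'   `time` (seconds from run start; TR sample i sits at its interval
#'   midpoint `(i - 1/2) * tr`), `tr`, `session_id`, `roi_label`; class
#'   `upsampled_series`.
#' @export
preprocess_timecourse <- function(series, upsample = 10) {
  if (!inherits(series, "roi_timeseries")) stop_param("series must be roi_timeseries")
  y <- series$values
  n <- length(y)
  conf <- as.matrix(series$confounds)
  all_zero <- apply(conf, 2, function(col) all(col == 0))
  constant <- apply(conf, 2, function(col) stats::sd(col) == 0) & !all_zero
  if (any(constant)) {
    warning("dropping constant confound column(s) collinear with the intercept")
  }
  X <- cbind(1, conf[, !(all_zero | constant), drop = FALSE])
  resid <- stats::lm.fit(X, y)$residuals
  # TR sample i lives at the interval midpoint (i - 1/2) * tr, matching the
  # sampling convention of the simulator and the design matrix
  t_coarse <- (seq_len(n) - 0.5) * series$tr
  dt <- series$tr / upsample
  t_fine <- seq(0, n * series$tr - dt, by = dt)
  vals <- stats::approx(t_coarse, resid, xout = t_fine, rule = 2)$y
  structure(list(values = vals, dt = dt, time = t_fine, tr = series$tr,
                 session_id = series$session_id, roi_label = series$roi_label),
            class = "upsampled_series")
}

#' Extract trial epochs from an upsampled series
#'
#' Cuts one row per trial, time-locked to the grid point nearest each onset,
#' spanning `[0, window]` seconds (`floor(window/dt) + 1` columns). Trials
#' whose window would run past the end of the series are excluded with a
#' warning.
#'
#' @param series_up An `upsampled_series` (or a plain numeric vector plus
#'   `dt`).
#' @param onsets Event onsets in seconds.
#' @param window Epoch length in seconds (default 7).
#' @param dt Sample spacing, taken from `series_up` when available.
#' @return An `epoch_matrix`: matrix trials x timepoints with attributes
#'   `time_axis`, `dt`, `kept` (logical per input onset), `session_id`.
#' @export
extract_epochs <- function(series_up, onsets, window = 7, dt = NULL) {
  if (inherits(series_up, "upsampled_series")) {
    vals <- series_up$values
    dt <- series_up$dt
    sid <- series_up$session_id
  } else {
    vals <- as.numeric(series_up)
    if (is.null(dt)) stop_param("dt required for a plain numeric series")
    sid <- NA_character_
  }
  n_col <- floor(window / dt) + 1
  start <- round(onsets / dt) + 1
  kept <- start >= 1 & (start + n_col - 1) <= length(vals)
  if (any(!kept)) {
    warning(sprintf("excluding %d trial(s) whose epoch runs outside the series",
                    sum(!kept)))
  }
  rows <- which(kept)
  data <- matrix(NA_real_, length(rows), n_col)
  for (i in seq_along(rows)) {
    a <- start[rows[i]]
    data[i, ] <- vals[a:(a + n_col - 1)]
  }
  structure(data,
            time_axis = (seq_len(n_col) - 1) * dt,
            dt = dt, kept = kept, session_id = sid,
            class = c("epoch_matrix", "matrix"))
}

# least-squares betas for Y (trials x T) on X (trials x p); returns p x T
ls_betas <- function(X, Y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_param("regression design is rank deficient; column(s): ",
               paste(bad, collapse = ", "))
  }
  qr.coef(qr_x, Y)
}

#' Per-timepoint regression of epoched activity
#'
#' At each epoch timepoint, fits BOLD on `[1, trialtype, rt]` across trials
#' by least squares; concatenating the trialtype coefficient over timepoints
#' gives the session's beta time course. The trialtype regressor codes the
#' contrast of interest (direction non-repeat = 1 vs repeat = 0 in the
#' repetition design; incongruent = 1 vs congruent = 0 in the
#' gaze-versus-object task).
#'
#' @param epochs An `epoch_matrix`.
#' @param trialtype Binary 0/1 vector, one per epoch row.
#' @param rt Optional reaction times (z-scored internally), one per row.
#' @return A `beta_timecourse`: matrix predictors x timepoints with
#'   `predictor_names`, `time_axis`, `session_id` attributes.
#' @export
beta_timecourse <- function(epochs, trialtype, rt = NULL) {
  Y <- unclass(epochs)
  if (length(trialtype) != nrow(Y)) stop_param("trialtype length must match epochs rows")
  if (!all(trialtype %in% c(0, 1))) stop_param("trialtype must be binary 0/1")
  if (length(unique(trialtype)) < 2) {
    stop_param("regression design is rank deficient; column(s): trialtype")
  }
  X <- cbind(intercept = 1, trialtype = trialtype)
  if (!is.null(rt)) X <- cbind(X, rt = zscore(rt))
  B <- ls_betas(X, Y)
  structure(B,
            predictor_names = colnames(X),
            time_axis = attr(epochs, "time_axis"),
            session_id = attr(epochs, "session_id"),
            class = c("beta_timecourse", "matrix"))
}

#' Per-timepoint psychophysiological interaction regression
#'
#' At each timepoint, fits the target ROI's activity on `[1, incongruency,
#' physio, incongruency x physio]`, where the physiological regressor is the
#' source ROI's activity at the same trial and timepoint. The interaction
#' coefficient measures how incongruency changes the coupling between the
#' two regions.
#'
#' @param target_epochs `epoch_matrix` of the target ROI.
#' @param incongruency Binary 0/1 vector per trial.
#' @param physio_epochs `epoch_matrix` of the source ROI (same trials and
#'   time axis).
#' @return A `beta_timecourse` with rows `intercept`, `incongruency`,
#'   `physio`, `incongruency:physio`.
#' @export
ppi_timecourse <- function(target_epochs, incongruency, physio_epochs) {
  Y <- unclass(target_epochs)
  P <- unclass(physio_epochs)
  if (!all(dim(Y) == dim(P))) stop_param("target and physio epochs must share dimensions")
  if (length(incongruency) != nrow(Y)) stop_param("incongruency length must match trials")
  if (length(unique(incongruency)) < 2) {
    stop_param("regression design is rank deficient; column(s): incongruency")
  }
  n_t <- ncol(Y)
  B <- matrix(NA_real_, 4, n_t)
  for (j in seq_len(n_t)) {
    X <- cbind(intercept = 1, incongruency = incongruency,
               physio = P[, j], `incongruency:physio` = incongruency * P[, j])
    B[, j] <- ls_betas(X, Y[, j, drop = FALSE])
  }
  structure(B,
            predictor_names = c("intercept", "incongruency", "physio",
                                "incongruency:physio"),
            time_axis = attr(target_epochs, "time_axis"),
            session_id = attr(target_epochs, "session_id"),
            class = c("beta_timecourse", "matrix"))
}

#' Permutation inference on a cross-session beta time course
#'
#' The observed statistic at each timepoint is the cross-session mean of the
#' chosen predictor's beta. Under the null, trial labels (trialtype or
#' incongruency) are shuffled within each session - leaving reaction times
#' and physiological rows paired to their trials - the per-timepoint
#' regressions are refit, and the session average recomputed; repeating this
#' `n_perm` times gives the null distribution. Two-sided p-values use the
#' add-one estimator `(1 + #{|null| >= |obs|}) / (1 + n_perm)` over the test
#' window (event onset to the hemodynamic peak, 3 s), and
#' Benjamini-Hochberg FDR is applied across timepoints within that window.
#'
#' @param sessions List, one element per session, each a list with `epochs`
#'   (`epoch_matrix`), `labels` (binary per trial), optional `rt`, and
#'   optional `physio` (`epoch_matrix`; switches the model to the PPI form
#'   with the interaction as the tested predictor).
#' @param n_perm Number of permutations (>= 100; 1000 in the full
#'   procedure).
#' @param window Test window in seconds (default 3).
#' @param seed Integer seed for the permutation stream.
#' @return A `perm_result`: list with `observed`, `null_distribution`
#'   (`n_perm` x timepoints), `p_raw`, `p_fdr` (NA outside the window),
#'   `time_axis`, `test_window`, `n_perm`, `predictor`.
#' @export
permutation_inference <- function(sessions, n_perm = 1000, window = 3, seed = 1) {
  if (n_perm < 100) stop_param("n_perm must be >= 100")
  sessions <- Filter(function(s) {
    tab <- table(s$labels)
    ok <- length(tab) == 2 && min(tab) >= 2
    if (!ok) warning("excluding a session with < 2 trials per label")
    ok
  }, sessions)
  if (!length(sessions)) stop_param("no usable sessions")

  time_axis <- attr(sessions[[1]]$epochs, "time_axis")
  n_t <- length(time_axis)
  ppi <- !is.null(sessions[[1]]$physio)
  predictor <- if (ppi) "incongruency:physio" else "trialtype"

  session_beta <- function(s, labels) {
    if (ppi) {
      b <- ppi_timecourse(s$epochs, labels, s$physio)
      b["incongruency:physio" == attr(b, "predictor_names"), ]
    } else {
      b <- beta_timecourse(s$epochs, labels, s$rt)
      b["trialtype" == attr(b, "predictor_names"), ]
    }
  }

  observed <- rowMeans(vapply(sessions, function(s) session_beta(s, s$labels),
                              numeric(n_t)))

  old <- .Random.seed_guard(derive_seed(seed, "permutation"))
  on.exit(old(), add = TRUE)
  null_dist <- matrix(NA_real_, n_perm, n_t)
  for (b in seq_len(n_perm)) {
    per_sess <- vapply(sessions, function(s) {
      session_beta(s, sample(s$labels))
    }, numeric(n_t))
    null_dist[b, ] <- rowMeans(per_sess)
  }

  in_window <- time_axis <= window + 1e-9
  p_raw <- rep(NA_real_, n_t)
  for (j in which(in_window)) {
    p_raw[j] <- (1 + sum(abs(null_dist[, j]) >= abs(observed[j]))) / (1 + n_perm)
  }
  p_fdr <- rep(NA_real_, n_t)
  p_fdr[in_window] <- stats::p.adjust(p_raw[in_window], method = "BH")

  structure(list(observed = observed, null_distribution = null_dist,
                 p_raw = p_raw, p_fdr = p_fdr, time_axis = time_axis,
                 test_window = window, n_perm = n_perm, predictor = predictor,
                 n_sessions = length(sessions)),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  sig <- sum(x$p_fdr <= 0.05, na.rm = TRUE)
  cat(sprintf("<perm_result> %s: %d sessions, %d permutations, window [0, %g] s\n",
              x$predictor, x$n_sessions, x$n_perm, x$test_window))
  cat(sprintf("  min p_fdr = %.4g; %d/%d windowed timepoints significant at 0.05\n",
              suppressWarnings(min(x$p_fdr, na.rm = TRUE)), sig,
              sum(!is.na(x$p_fdr))))
  invisible(x)
}

#' Holm-Bonferroni correction across regions of interest
#'
#' Step-down Holm adjustment with monotonicity enforcement, applied to one
#' p-value per ROI (e.g. each ROI's minimum FDR-corrected p within the test
#' window, or the p at a fixed timepoint).
#'
#' @param p_per_roi Named numeric vector or list of p-values, one per ROI.
#' @return Named numeric vector of adjusted p-values.
#' @export
holm_across_rois <- function(p_per_roi) {
  p <- unlist(p_per_roi)
  if (!length(p)) stop_param("p_per_roi must not be empty")
  if (any(!is.finite(p))) stop_param("p values must be finite")
  stats::setNames(stats::p.adjust(p, method = "holm"), names(p))
}
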