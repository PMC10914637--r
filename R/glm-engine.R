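#' Build the event table for a GLM specification
#'
#' Expands one session's trials into named events (onset, duration,
#' amplitude, convolve flag) following the registered regressor sets:
#'
#' \describe{
#'   \item{GLM1 (two-face repetition design)}{`face` (first-face onset),
#'     `dsimFace`/`simFace` (decision onset on direction non-repeat / repeat
#'     trials), `RT` (z-scored, decision-locked), `leftResp`/`rightResp`,
#'     `outcome`, `binOutcome` (reward 1/0 at feedback), unconvolved
#'     `leftUnconv`/`rightUnconv`/`juice`, and `fchInvalid`/`schInvalid`
#'     (first/second face onsets on invalid trials). Convolved boxcars are
#'     500 ms; unconvolved columns last one TR.}
#'   \item{GLM2}{as GLM1 with regressors 2-3 keyed to identity repetition
#'     (`dsimIdentity`/`simIdentity`).}
#'   \item{GLM3 (gaze-versus-object task)}{`object`/`face` (decision onset on
#'     incongruent trials where the object/face was followed), `congruent`
#'     (all congruent decisions), `noResp`, `RTvalid`/`RTinvalid` (z-scored),
#'     `leftResp`/`rightResp`, `binOutcomeObject`/`binOutcomeFace`/
#'     `binOutcomeCong` (reward 1/0 at feedback per trial class), and
#'     unconvolved `leftUnconv`/`rightUnconv`/`juice`. Decision boxcars are
#'     1 s, outcome boxcars 2 s, unconvolved columns one TR.}
#' }
#'
#' @param trials One session's trial table (`make_exp1_schedule()` output for
#'   GLM1/GLM2; a completed gaze-versus-object session for GLM3).
#' @param spec `"GLM1"`, `"GLM2"` or `"GLM3"`.
#' @param tr Repetition time in seconds (sets unconvolved durations).
#' @return Data.frame with columns `name`, `onset`, `duration`, `amplitude`,
#'   `convolve`.
#' @export
build_event_table <- function(trials, spec = c("GLM3", "GLM1", "GLM2"), tr = 1.48) {
  spec <- match.arg(spec)
  if (spec %in% c("GLM1", "GLM2")) build_event_table_exp1(trials, spec, tr)
  else build_event_table_exp2(trials, tr)
}

ev_rows <- function(name, onset, duration, amplitude = 1, convolve = TRUE) {
  if (length(onset) == 0) return(NULL)
  data.frame(name = name, onset = onset, duration = duration,
             amplitude = rep_len(amplitude, length(onset)),
             convolve = convolve, stringsAsFactors = FALSE)
}

build_event_table_exp1 <- function(trials, spec, tr) {
  need <- c("onset_first_face", "onset_decision", "onset_outcome",
            "direction_repeat", "identity_repeat", "response_side", "rt",
            "valid", "rewarded")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop_param("trials lack required fields for ", spec, ": ",
               paste(missing, collapse = ", "))
  }
  v <- trials$valid
  iv <- !v
  rep_col <- if (spec == "GLM1") trials$direction_repeat else trials$identity_repeat
  lab <- if (spec == "GLM1") c("dsimFace", "simFace") else c("dsimIdentity", "simIdentity")
  dur <- 0.5
  rtz <- zscore(trials$rt[v])
  # motor-response regressors are locked to the movement itself (cue + RT);
  # locking them to the cue would duplicate the trial-class partition and
  # make the design singular in sessions without invalid trials
  move <- trials$onset_decision + pmin(trials$rt, 3)
  rbind(
    ev_rows("face", trials$onset_first_face[v], dur),
    ev_rows(lab[1], trials$onset_decision[v & !rep_col], dur),
    ev_rows(lab[2], trials$onset_decision[v & rep_col], dur),
    ev_rows("RT", trials$onset_decision[v], dur, amplitude = rtz),
    ev_rows("leftResp", move[trials$response_side == "left"], dur),
    ev_rows("rightResp", move[trials$response_side == "right"], dur),
    ev_rows("outcome", trials$onset_outcome[v], dur),
    ev_rows("binOutcome", trials$onset_outcome[v], dur,
            amplitude = as.numeric(trials$rewarded[v])),
    ev_rows("leftUnconv", move[trials$response_side == "left"],
            tr, convolve = FALSE),
    ev_rows("rightUnconv", move[trials$response_side == "right"],
            tr, convolve = FALSE),
    ev_rows("juice", trials$onset_outcome[v & trials$rewarded], tr, convolve = FALSE),
    ev_rows("fchInvalid", trials$onset_first_face[iv], dur),
    ev_rows("schInvalid", trials$onset_decision[iv], dur)
  )
}

build_event_table_exp2 <- function(trials, tr) {
  need <- c("onset_decision", "onset_outcome", "choice", "face_direction",
            "better_object_side", "rewarded_side", "congruent", "rt", "valid")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop_param("trials lack required fields for GLM3: ",
               paste(missing, collapse = ", "))
  }
  responded <- trials$choice != "none"
  v <- trials$valid & responded
  iv <- responded & !trials$valid
  followed_face <- responded & trials$choice == trials$face_direction
  incong <- !trials$congruent
  cls_face <- v & incong & followed_face
  cls_obj <- v & incong & !followed_face
  cls_cong <- v & trials$congruent
  rewarded <- responded & trials$choice == trials$rewarded_side
  dur_dec <- 1; dur_out <- 2
  rtz_v <- zscore(trials$rt[v])
  rtz_iv <- zscore(trials$rt[iv])
  # motor-response regressors locked to the movement (see Exp1 note)
  move <- trials$onset_decision + trials$rt
  rbind(
    ev_rows("object", trials$onset_decision[cls_obj], dur_dec),
    ev_rows("face", trials$onset_decision[cls_face], dur_dec),
    ev_rows("congruent", trials$onset_decision[cls_cong], dur_dec),
    ev_rows("noResp", trials$onset_decision[!responded], dur_dec),
    ev_rows("RTvalid", trials$onset_decision[v], dur_dec, amplitude = rtz_v),
    ev_rows("RTinvalid", trials$onset_decision[iv], dur_dec, amplitude = rtz_iv),
    ev_rows("leftResp", move[responded & trials$choice == "left"], dur_dec),
    ev_rows("rightResp", move[responded & trials$choice == "right"], dur_dec),
    ev_rows("binOutcomeObject", trials$onset_outcome[cls_obj], dur_out,
            amplitude = as.numeric(rewarded[cls_obj])),
    ev_rows("binOutcomeFace", trials$onset_outcome[cls_face], dur_out,
            amplitude = as.numeric(rewarded[cls_face])),
    ev_rows("binOutcomeCong", trials$onset_outcome[cls_cong], dur_out,
            amplitude = as.numeric(rewarded[cls_cong])),
    ev_rows("leftUnconv", move[responded & trials$choice == "left"],
            tr, convolve = FALSE),
    ev_rows("rightUnconv", move[responded & trials$choice == "right"],
            tr, convolve = FALSE),
    ev_rows("juice", trials$onset_outcome[rewarded], tr, convolve = FALSE)
  )
}

glm_registry <- list(
  GLM1 = c("face", "dsimFace", "simFace", "RT", "leftResp", "rightResp",
           "outcome", "binOutcome", "leftUnconv", "rightUnconv", "juice",
           "fchInvalid", "schInvalid"),
  GLM2 = c("face", "dsimIdentity", "simIdentity", "RT", "leftResp", "rightResp",
           "outcome", "binOutcome", "leftUnconv", "rightUnconv", "juice",
           "fchInvalid", "schInvalid"),
  GLM3 = c("object", "face", "congruent", "noResp", "RTvalid", "RTinvalid",
           "leftResp", "rightResp", "binOutcomeObject", "binOutcomeFace",
           "binOutcomeCong", "leftUnconv", "rightUnconv", "juice")
)

#' Build a time-by-regressor design matrix
#'
#' Converts an event table (or a trial table, via [build_event_table()]) into
#' the design matrix of the chosen GLM: each regressor's events are laid down
#' as boxcars on a fine grid (`tr/10`), convolved-flagged columns are
#' convolved with the gamma HRF, and all columns are sampled at TR midpoints.
#' Registered regressors that end up with no events (e.g. no invalid trials)
#' are dropped with a warning rather than kept as zero columns, preserving
#' full rank. Confound columns are appended unconvolved as-is.
#'
#' @param trials Trial table for one session (see [build_event_table()]), or
#'   an event table with the five event columns.
#' @param spec `"GLM1"`, `"GLM2"` or `"GLM3"`.
#' @param confounds Optional numeric matrix (`n_timepoints` rows) appended as
#'   nuisance columns.
#' @param tr Repetition time in seconds.
#' @param n_timepoints Number of TR samples the target series has.
#' @return An object of class `design_matrix`: list with `X`, `column_names`,
#'   `convolved_mask`, `tr`, `dropped`.
#' @export
build_design <- function(trials, spec = c("GLM3", "GLM1", "GLM2"),
                         confounds = NULL, tr = 1.48, n_timepoints) {
  spec <- match.arg(spec)
  events <- if (all(c("name", "onset", "duration", "amplitude", "convolve")
                    %in% names(trials))) trials
            else build_event_table(trials, spec, tr)
  if (any(events$onset < 0)) stop_param("event onsets must be >= 0")
  if (any(events$duration <= 0)) stop_param("event durations must be > 0")

  registry <- glm_registry[[spec]]
  unknown <- setdiff(unique(events$name), registry)
  if (length(unknown)) {
    stop_param("events carry names outside the ", spec, " registry: ",
               paste(unknown, collapse = ", "))
  }
  present <- registry[registry %in% events$name]
  dropped <- setdiff(registry, present)
  if (length(dropped)) {
    warning(sprintf("%s: dropping empty regressor(s): %s", spec,
                    paste(dropped, collapse = ", ")))
  }

  up <- 10L
  dt <- tr / up
  n_fine <- n_timepoints * up
  kernel <- hrf_kernel(dt = dt)
  idx <- tr_sample_index(n_timepoints, up)

  X <- matrix(0, n_timepoints, length(present),
              dimnames = list(NULL, present))
  conv_mask <- logical(length(present))
  for (j in seq_along(present)) {
    e <- events[events$name == present[j], ]
    conv <- e$convolve[1]
    fine <- event_boxcar(e$onset, e$duration, e$amplitude, n_fine, dt)
    if (conv) fine <- convolve_fine(fine, kernel, dt)
    X[, j] <- fine[idx]
    conv_mask[j] <- conv
  }
  # amplitude-coded regressors whose events were all zero (e.g. no rewarded
  # trial in a class) reduce to zero columns; drop them like empty regressors
  zero_col <- apply(X, 2, function(col) all(col == 0))
  if (any(zero_col)) {
    warning(sprintf("%s: dropping all-zero regressor(s): %s", spec,
                    paste(present[zero_col], collapse = ", ")))
    dropped <- c(dropped, present[zero_col])
    X <- X[, !zero_col, drop = FALSE]
    conv_mask <- conv_mask[!zero_col]
    present <- present[!zero_col]
  }

  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n_timepoints) {
      stop_param("confounds must have n_timepoints rows")
    }
    cn <- colnames(confounds) %||% paste0("confound_", seq_len(ncol(confounds)))
    if (is.null(colnames(confounds))) colnames(confounds) <- cn
    X <- cbind(X, confounds)
    conv_mask <- c(conv_mask, rep(FALSE, ncol(confounds)))
  }
  if (anyDuplicated(colnames(X))) stop_param("duplicated design column names")

  structure(list(X = X, column_names = colnames(X), convolved_mask = conv_mask,
                 tr = tr, spec = spec, dropped = dropped),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %s: %d timepoints x %d columns (tr=%.3gs)\n",
              x$spec, nrow(x$X), ncol(x$X), x$tr))
  cat("  columns:", paste(x$column_names, collapse = ", "), "\n")
  if (length(x$dropped)) cat("  dropped :", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' High-pass filter a series by Gaussian-weighted running-line removal
#'
#' At each timepoint a weighted linear trend is fit with Gaussian weights of
#' width `sigma = sqrt(2 log 2) * cutoff / (2 pi)` seconds and subtracted, so
#' the filter has half-amplitude response at the cutoff frequency: a sine at
#' twice the cutoff period is mostly removed while one at a fifth of the
#' cutoff period passes nearly untouched. The same filter must be applied to
#' the data series and the convolved design columns.
#'
#' @param series Numeric vector sampled at `tr`.
#' @param tr Sampling interval in seconds.
#' @param cutoff High-pass cutoff period in seconds (> 2 * tr).
#' @return Filtered series (trend removed; zero mean for a constant input).
#' @export
highpass_filter <- function(series, tr, cutoff = 100) {
  if (cutoff <= 2 * tr) stop_param("cutoff must exceed 2 * tr")
  n <- length(series)
  if (n < cutoff / tr) {
    warning("series shorter than one cutoff period; filter skipped")
    return(series)
  }
  sigma <- sqrt(2 * log(2)) * cutoff / (2 * pi)
  t <- (seq_len(n) - 1) * tr
  half_win <- 4 * sigma
  out <- numeric(n)
  for (i in seq_len(n)) {
    sel <- which(abs(t - t[i]) <= half_win)
    w <- exp(-((t[sel] - t[i])^2) / (2 * sigma^2))
    tc <- t[sel] - t[i]
    sw <- sum(w); swx <- sum(w * tc); swxx <- sum(w * tc^2)
    swy <- sum(w * series[sel]); swxy <- sum(w * tc * series[sel])
    det <- sw * swxx - swx^2
    trend_i <- (swxx * swy - swx * swxy) / det
    out[i] <- series[i] - trend_i
  }
  out
}

#' Apply the high-pass filter to a design matrix
#'
#' Convolved task columns are filtered identically to the data; unconvolved
#' spike/confound columns are left untouched.
#'
#' @param design A `design_matrix`.
#' @param cutoff Cutoff period in seconds.
#' @return The filtered `design_matrix`.
#' @export
highpass_design <- function(design, cutoff = 100) {
  for (j in which(design$convolved_mask)) {
    design$X[, j] <- highpass_filter(design$X[, j], design$tr, cutoff)
  }
  design
}

#' Fit a session-level GLM by least squares
#'
#' @param series `roi_timeseries` or numeric vector (already high-pass
#'   filtered to match the design).
#' @param design A `design_matrix` with matching row count. An intercept
#'   column is added.
#' @return An object of class `glm_fit`: `betas` (named), `residuals`,
#'   `sigma2`, `dof`, `column_names`.
#' @export
fit_glm <- function(series, design) {
  y <- if (inherits(series, "roi_timeseries")) series$values else as.numeric(series)
  X <- cbind(`(Intercept)` = 1, design$X)
  if (nrow(X) != length(y)) stop_param("series and design lengths differ")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_param("design is rank deficient; collinear column(s): ",
               paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qr_x, y)
  res <- y - as.numeric(X %*% betas)
  dof <- length(y) - ncol(X)
  structure(list(betas = betas, residuals = res,
                 sigma2 = sum(res^2) / dof, dof = dof,
                 column_names = colnames(X)),
            class = "glm_fit")
}

#' Random-effects group contrast across sessions
#'
#' Computes a contrast of betas per session and summarizes across sessions
#' with a one-sample t-test, treating sessions as the random-effects unit (a
#' summary-statistics analogue of multi-stage mixed-effects group
#' inference). Contrast entries are matched by design column name; columns a
#' session lacks (dropped empty regressors) must have zero contrast weight.
#'
#' @param session_fits List of `glm_fit` objects.
#' @param contrast Named numeric vector of contrast weights over task
#'   columns (unnamed columns get weight 0).
#' @return List with `estimate` (mean contrast), `se`, `t`, `df`, `p`
#'   (two-sided), `per_session`, and `degenerate` (TRUE when between-session
#'   variance is zero, in which case `t`/`p` are NA and `all_equal` reports
#'   the common value).
#' @export
contrast_group <- function(session_fits, contrast) {
  if (length(session_fits) < 3) stop_param("need >= 3 sessions for group inference")
  if (is.null(names(contrast))) stop_param("contrast must be a named vector")
  vals <- vapply(session_fits, function(fit) {
    w <- stats::setNames(numeric(length(fit$betas)), fit$column_names)
    hit <- intersect(names(contrast), names(w))
    miss <- setdiff(names(contrast)[contrast != 0], fit$column_names)
    if (length(miss)) {
      stop_param("contrast names a column absent from a session fit: ",
                 paste(miss, collapse = ", "))
    }
    w[hit] <- contrast[hit]
    sum(w * fit$betas)
  }, numeric(1))
  n <- length(vals)
  m <- mean(vals)
  s <- stats::sd(vals)
  if (s == 0) {
    return(list(estimate = m, se = 0, t = NA_real_, df = n - 1, p = NA_real_,
                per_session = vals, degenerate = TRUE, all_equal = m))
  }
  se <- s / sqrt(n)
  tval <- m / se
  list(estimate = m, se = se, t = tval, df = n - 1,
       p = 2 * stats::pt(-abs(tval), n - 1),
       per_session = vals, degenerate = FALSE)
}
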