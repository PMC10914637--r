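#' @importFrom lmerTest lmer
#' @importFrom lme4 glmer isSingular VarCorr
NULL

# ---------------------------------------------------------------------------
# Internal engine shared by the four behavioral models.
#
# Fits `formula` with independent per-session random intercept/slopes by ML.
# Follows the estimation rules of the analysis: Satterthwaite F-tests on each
# fixed effect; if the fit is singular or the optimizer Hessian is not
# positive definite, refit with every term as a fixed effect (ordinary
# least squares) and flag it; with a single session, refuse random effects
# outright.
fit_mixed <- function(formula_fixed, data, link = c("linear", "logistic"),
                      response) {
  link <- match.arg(link)
  sessions <- unique(data$session_id)
  rhs <- attr(stats::terms(formula_fixed), "term.labels")
  rhs_str <- if (length(rhs)) paste(rhs, collapse = " + ") else "1"
  single_session <- length(sessions) < 2

  fell_back <- FALSE
  hessian_pd <- TRUE
  converged <- TRUE
  model <- NULL

  if (single_session) {
    warning("single session: fitting fixed effects only (no random effects)")
    fell_back <- TRUE
  } else {
    ff <- stats::as.formula(paste(response, "~", rhs_str,
                                  "+ (1 +", rhs_str, "|| session_id)"))
    if (link == "linear") {
      model <- tryCatch(
        suppressMessages(suppressWarnings(
          lmerTest::lmer(ff, data = data, REML = FALSE))),
        error = function(e) NULL)
    } else {
      model <- tryCatch(
        suppressWarnings(lme4::glmer(ff, data = data, family = stats::binomial())),
        error = function(e) NULL)
    }
    if (is.null(model)) {
      hessian_pd <- FALSE
      fell_back <- TRUE
    } else {
      hessian_pd <- hessian_positive_definite(model)
      if (!hessian_pd) fell_back <- TRUE
    }
  }

  if (fell_back) {
    model <- fit_all_fixed(formula_fixed, data, link, response)
  }

  if (link == "logistic" && !fell_back) {
    # detect separation: absurd coefficient scale -> fall back to linear link
    est <- lme4::fixef(model)
    if (any(abs(est) > 15)) {
      warning("separation detected under logistic link; falling back to linear link")
      return(fit_mixed(formula_fixed, data, link = "linear", response = response))
    }
  }

  fe <- extract_fixed_effects(model, link, fell_back)
  re_sds <- extract_re_sds(model, fell_back)

  structure(list(
    fixed_effects = fe,
    random_effect_sds = re_sds,
    loglik = as.numeric(stats::logLik(model)),
    converged = converged,
    hessian_pd = hessian_pd,
    fell_back_to_fixed = fell_back,
    ks_p = NA_real_,
    link = link,
    n_sessions = length(sessions),
    n_trials = nrow(data),
    model = model
  ), class = "cue_mixed_fit")
}

fit_all_fixed <- function(formula_fixed, data, link, response) {
  ff <- stats::as.formula(paste(response, "~",
                                paste(attr(stats::terms(formula_fixed), "term.labels"),
                                      collapse = " + ")))
  if (link == "linear") stats::lm(ff, data = data)
  else stats::glm(ff, data = data, family = stats::binomial())
}

# Positive definiteness of the optimizer's Hessian at the optimum. A
# variance estimated exactly at the boundary (a "singular" fit) does not by
# itself fail this check: the constrained Hessian there is usually still PD
# and the remaining variance components stay reliably estimated. Only a
# genuinely non-PD Hessian (or a failed fit) triggers the all-fixed
# fallback.
hessian_positive_definite <- function(model, tol = 1e-6) {
  h <- model@optinfo$derivs$Hessian
  if (is.null(h)) return(TRUE)
  ev <- tryCatch(eigen(as.matrix(h), symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  all(is.finite(ev)) && min(ev) > tol
}

extract_fixed_effects <- function(model, link, fell_back) {
  if (inherits(model, "lmerModLmerTest")) {
    co <- summary(model)$coefficients  # Estimate, SE, df (Satterthwaite), t, p
    df2 <- co[, "df"]
    tval <- co[, "t value"]
    p <- co[, "Pr(>|t|)"]
  } else if (inherits(model, "glmerMod")) {
    co <- summary(model)$coefficients
    df2 <- rep(Inf, nrow(co))
    tval <- co[, "z value"]
    p <- co[, "Pr(>|z|)"]
  } else {  # lm / glm
    co <- summary(model)$coefficients
    df2 <- rep(stats::df.residual(model), nrow(co))
    tval <- co[, 3]
    p <- co[, 4]
  }
  est <- co[, 1]; se <- co[, 2]
  tcrit <- ifelse(is.finite(df2), stats::qt(0.975, pmax(df2, 1)), stats::qnorm(0.975))
  data.frame(
    term = rownames(co),
    estimate = est,
    se = se,
    ci_low = est - tcrit * se,
    ci_high = est + tcrit * se,
    f = tval^2,
    df1 = 1,
    df2 = as.numeric(df2),
    p = p,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

extract_re_sds <- function(model, fell_back) {
  if (fell_back || !(inherits(model, "lmerMod") || inherits(model, "glmerMod") ||
                     inherits(model, "lmerModLmerTest"))) {
    return(numeric(0))
  }
  vc <- lme4::VarCorr(model)
  sds <- unlist(lapply(vc, function(m) attr(m, "stddev")))
  stats::setNames(as.numeric(sds), make.unique(names(sds)))
}

#' @export
print.cue_mixed_fit <- function(x, ...) {
  cat(sprintf("<cue_mixed_fit> link=%s sessions=%d trials=%d%s%s\n",
              x$link, x$n_sessions, x$n_trials,
              if (x$fell_back_to_fixed) " [all-fixed fallback]" else "",
              if (!is.na(x$ks_p)) sprintf(" ks_p=%.3f", x$ks_p) else ""))
  print(x$fixed_effects, digits = 3)
  invisible(x)
}

#' Coefficient table of a behavioral model fit
#'
#' @param fit A `cue_mixed_fit`.
#' @return Its `fixed_effects` data.frame.
#' @export
coef_table <- function(fit) fit$fixed_effects

# ---------------------------------------------------------------------------

prepare_choice_data <- function(trials) {
  trials <- trials[trials$choice != "none" & !is.na(trials$choice), , drop = FALSE]
  data.frame(
    session_id = factor(trials$session_id),
    choice = side_code(trials$choice),
    choice01 = as.integer(trials$choice == "right"),
    facedirection = side_code(trials$face_direction),
    objectdirection = side_code(trials$better_object_side),
    incongruency = as.numeric(!trials$congruent),
    accuracy = trials$accuracy,
    roi = as.numeric(trials$tus_site != "sham")
  )
}

#' Choice model: face and object influence on choice
#'
#' Regresses trial-wise choice on face direction, the side of the better
#' object, and their interaction, with independent per-session random
#' intercept and slopes. The default linear-probability link matches the
#' model's printed linear form and makes the coefficients directly comparable
#' to generative linear-policy weights; a logistic link is available.
#'
#' Sides are coded -1/+1; under the linear link the choice is also coded
#' -1/+1, under the logistic link 0/1.
#'
#' @param trials Completed trial table (one condition; invalid/no-response
#'   trials are excluded).
#' @param condition Optional condition filter.
#' @param link `"linear"` (default) or `"logistic"`.
#' @return A `cue_mixed_fit`.
#' @export
fit_choice_model <- function(trials, condition = NULL,
                             link = c("linear", "logistic")) {
  link <- match.arg(link)
  if (!is.null(condition)) trials <- trials[trials$condition == condition, ]
  d <- prepare_choice_data(trials)
  response <- if (link == "linear") "choice" else "choice01"
  fit_mixed(~ facedirection * objectdirection, d, link = link, response = response)
}

#' Accuracy-on-incongruency model
#'
#' Regresses accuracy (0/1) on trial incongruency (0 congruent, 1
#' incongruent) with per-session random intercept and slope; the incongruency
#' coefficient measures how much conflict between the cues costs in accuracy.
#'
#' @param trials Completed trial table, typically one condition.
#' @param condition Optional condition filter.
#' @return A `cue_mixed_fit`; the `incongruency` row is the effect of
#'   interest.
#' @export
fit_accuracy_congruency_model <- function(trials, condition = NULL) {
  if (!is.null(condition)) trials <- trials[trials$condition == condition, ]
  d <- prepare_choice_data(trials)
  if (length(unique(d$incongruency)) < 2) {
    stop("incongruency is constant in these trials; model is rank deficient")
  }
  fit_mixed(~ incongruency, d, link = "linear", response = "accuracy")
}

#' Stimulation effect on accuracy
#'
#' Pools sham sessions (ROI = 0) with one active stimulation site (ROI = 1)
#' and regresses accuracy on the ROI indicator, either within a
#' congruent/incongruent trial subset or, with `with_interaction = TRUE`, on
#' ROI, incongruency and their interaction over all trials.
#'
#' @param trials Trial table containing sham and active-site sessions.
#' @param site Active site, `"dmFPC"`, `"mSTS"` or `"EVC"`.
#' @param trial_subset `"congruent"`, `"incongruent"` or `"all"`.
#' @param with_interaction Add incongruency and ROI x incongruency terms.
#' @param condition Optional condition filter.
#' @return A `cue_mixed_fit`; the `roi` row is the stimulation effect.
#' @export
fit_tus_accuracy_model <- function(trials, site,
                                   trial_subset = c("incongruent", "congruent", "all"),
                                   with_interaction = FALSE, condition = NULL) {
  site <- match.arg(site, c("dmFPC", "mSTS", "EVC"))
  trial_subset <- match.arg(trial_subset)
  if (!is.null(condition)) trials <- trials[trials$condition == condition, ]
  if (!any(trials$tus_site == "sham")) stop_param("no sham sessions in trials")
  trials <- trials[trials$tus_site %in% c("sham", site), ]
  if (!with_interaction && trial_subset != "all") {
    keep <- if (trial_subset == "congruent") trials$congruent else !trials$congruent
    trials <- trials[keep, ]
  }
  d <- prepare_choice_data(trials)
  if (with_interaction) {
    fit_mixed(~ roi * incongruency, d, link = "linear", response = "accuracy")
  } else {
    fit_mixed(~ roi, d, link = "linear", response = "accuracy")
  }
}

#' Stimulation effect on cue weighting
#'
#' Tests whether stimulation changes the contribution of a cue to choice:
#' choice is regressed on the cue direction, the ROI indicator and their
#' interaction; the interaction coefficient is the stimulation-induced change
#' in the cue's weight.
#'
#' @param trials Trial table with sham and one active site.
#' @param site Active site.
#' @param cue `"face"` (face direction) or `"object"` (better-object side).
#' @param condition Optional condition filter.
#' @return A `cue_mixed_fit`; the cue-by-roi interaction row is the effect of
#'   interest.
#' @export
fit_tus_choice_model <- function(trials, site, cue = c("face", "object"),
                                 condition = NULL) {
  site <- match.arg(site, c("dmFPC", "mSTS", "EVC"))
  cue <- match.arg(cue)
  if (!is.null(condition)) trials <- trials[trials$condition == condition, ]
  if (!any(trials$tus_site == "sham")) stop_param("no sham sessions in trials")
  trials <- trials[trials$tus_site %in% c("sham", site), ]
  d <- prepare_choice_data(trials)
  d$cuedirection <- if (cue == "face") d$facedirection else d$objectdirection
  fit_mixed(~ cuedirection * roi, d, link = "linear", response = "choice")
}

#' Model diagnostics: residual normality and nested-model comparison
#'
#' Annotates a fit with the Kolmogorov-Smirnov p-value for residual
#' normality (residuals standardized against their own mean and SD) and,
#' optionally, a likelihood-ratio comparison against a nested reduced fit.
#'
#' @param fit A `cue_mixed_fit`.
#' @param reduced Optional nested `cue_mixed_fit` (fewer parameters, same
#'   data) for a likelihood-ratio test.
#' @return The fit, with `ks_p` set and (if `reduced` given) an `lr_test`
#'   element `list(statistic, df, p)`.
#' @export
check_model_diagnostics <- function(fit, reduced = NULL) {
  r <- stats::residuals(fit$model)
  s <- stats::sd(r)
  if (s > 0) {
    fit$ks_p <- suppressWarnings(
      stats::ks.test(as.numeric(r), "pnorm", mean(r), s)$p.value)
  } else {
    fit$ks_p <- NA_real_
  }
  if (!is.null(reduced)) {
    df_full <- attr(stats::logLik(fit$model), "df")
    df_red <- attr(stats::logLik(reduced$model), "df")
    if (df_red >= df_full || fit$n_trials != reduced$n_trials) {
      stop_param("reduced model must be nested in the full model (same data, fewer parameters)")
    }
    stat <- 2 * (fit$loglik - reduced$loglik)
    df <- df_full - df_red
    fit$lr_test <- list(statistic = stat, df = df,
                        p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  fit
}
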