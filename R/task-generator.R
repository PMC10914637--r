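#' Default cue reliabilities per condition
#'
#' The gaze-versus-object task has three 50-trial block conditions with
#' asymmetric cue reliabilities: in the Face condition the face points at the
#' rewarded object on 90% of trials while the better object is rewarded on
#' only 60%; in the Object condition the proportions are reversed; in the
#' Mixed condition both cues are 90% reliable.
#'
#' @param condition `"Face"`, `"Object"` or `"Mixed"`.
#' @return Named numeric vector `c(face = , object = )`.
#' @export
condition_reliabilities <- function(condition) {
  switch(match.arg(condition, c("Face", "Object", "Mixed")),
    Face   = c(face = 0.9, object = 0.6),
    Object = c(face = 0.6, object = 0.9),
    Mixed  = c(face = 0.9, object = 0.9)
  )
}

#' Generate one session block of the gaze-versus-object task
#'
#' Draws, independently per trial: the side of the better object (uniform),
#' the rewarded side (equal to the better-object side with probability
#' `p_object`), and the face direction (equal to the rewarded side with
#' probability `p_face`). A trial is congruent when the face points at the
#' better object. Event onsets accumulate over trials using a nominal 1 s
#' response slot, an action-outcome delay and an inter-trial interval drawn
#' uniformly from the configured ranges; [simulate_agent_choices()] replaces
#' the nominal slot with realized reaction times.
#'
#' @param condition Block condition, `"Face"`, `"Object"` or `"Mixed"`.
#' @param n_trials Number of trials (default 50, one block).
#' @param reliabilities Length-2 numeric `(p_face, p_object)`; defaults to
#'   [condition_reliabilities()].
#' @param seed Integer seed for this session's stream.
#' @param session_id Session identifier string.
#' @param tus_site `"sham"`, `"dmFPC"`, `"mSTS"` or `"EVC"` label carried on
#'   every trial (which agent perturbation, if any, was applied).
#' @param experiment `"exp2"` (delay 3-5 s, ITI 3-4 s) or `"exp3"` (delay
#'   300 ms, ITI 3-5 s).
#' @param iti_range,delay_range Optional length-2 overrides (seconds).
#' @return A `data.frame` of trial records with unset choice fields
#'   (`choice = "none"`, `accuracy = NA`, `rt = NA`).
#' @export
make_session_schedule <- function(condition, n_trials = 50, reliabilities = NULL,
                                  seed = 1, session_id = "s01",
                                  tus_site = "sham",
                                  experiment = c("exp2", "exp3"),
                                  iti_range = NULL, delay_range = NULL) {
  condition <- match.arg(condition, c("Face", "Object", "Mixed"))
  experiment <- match.arg(experiment)
  tus_site <- match.arg(tus_site, c("sham", "dmFPC", "mSTS", "EVC"))
  if (!is.numeric(n_trials) || n_trials < 1) stop_param("n_trials must be >= 1")
  if (is.null(reliabilities)) reliabilities <- condition_reliabilities(condition)
  if (length(reliabilities) != 2) stop_param("reliabilities must have length 2")
  check_prob(reliabilities, "reliabilities")
  p_face <- reliabilities[[1]]; p_object <- reliabilities[[2]]
  if (is.null(iti_range)) iti_range <- if (experiment == "exp2") c(3, 4) else c(3, 5)
  if (is.null(delay_range)) delay_range <- if (experiment == "exp2") c(3, 5) else c(0.3, 0.3)

  withr_seed <- derive_seed(seed, session_id, condition)
  old <- .Random.seed_guard(withr_seed)
  on.exit(old(), add = TRUE)

  better <- sample(c("left", "right"), n_trials, replace = TRUE)
  rew_match <- stats::runif(n_trials) < p_object
  rewarded <- ifelse(rew_match, better, other_side(better))
  face_match <- stats::runif(n_trials) < p_face
  face <- ifelse(face_match, rewarded, other_side(rewarded))

  delay <- stats::runif(n_trials, delay_range[1], delay_range[2])
  iti <- stats::runif(n_trials, iti_range[1], iti_range[2])
  # cue (face turn) comes 100 ms after trial start; nominal 1 s response slot
  nominal_rt <- rep(1, n_trials)
  onset_decision <- cue_onsets(nominal_rt, delay, iti, feedback_dur = 0.5)
  onset_outcome <- onset_decision + nominal_rt + delay

  trials <- data.frame(
    session_id = session_id,
    condition = condition,
    trial_index = seq_len(n_trials) - 1L,
    face_direction = face,
    better_object_side = better,
    rewarded_side = rewarded,
    congruent = face == better,
    choice = "none",
    accuracy = NA_integer_,
    rt = NA_real_,
    onset_decision = onset_decision,
    onset_outcome = onset_outcome,
    delay = delay,
    iti = iti,
    valid = NA,
    tus_site = tus_site,
    stringsAsFactors = FALSE
  )
  trials
}

other_side <- function(side) ifelse(side == "left", "right", "left")

# onset of the decision period (face turn) for each trial, given per-trial
# response durations; trial layout: 0.1 s neutral face, response, delay,
# 0.5 s feedback, ITI.
cue_onsets <- function(rt, delay, iti, feedback_dur = 0.5) {
  trial_len <- 0.1 + rt + delay + feedback_dur + iti
  starts <- c(0, cumsum(trial_len))[seq_along(rt)]
  starts + 0.1
}

# Set the RNG reproducibly and return a restore closure.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Label trial congruency
#'
#' A trial is incongruent when the face is directed away from the better of
#' the two objects; the label depends only on those two fields.
#'
#' @param trials Trial data.frame with `face_direction` and
#'   `better_object_side` set.
#' @return Logical vector, `TRUE` for congruent trials.
#' @export
label_congruency <- function(trials) {
  f <- trials$face_direction; b <- trials$better_object_side
  if (any(is.na(f)) || any(is.na(b))) {
    stop("face_direction/better_object_side must be set before labeling congruency")
  }
  f == b
}

#' Construct choice-agent parameters
#'
#' The synthetic agent chooses via a policy on the signed cues
#' (left = -1, right = +1). Policies:
#' \describe{
#'   \item{logistic}{P(right) = plogis(w_face * face + w_object * object +
#'     side_bias).}
#'   \item{linear}{P(right) = 0.5 + 0.5 * (w_face * face + w_object * object +
#'     side_bias), clipped to \[0, 1\]; under the symmetric choice coding the
#'     linear-link mixed model recovers these weights directly.}
#'   \item{mixture}{follow the face side with probability `follow_face_prob`,
#'     otherwise choose the better-object side.}
#' }
#' A lapse overrides the policy with a uniform choice. Reaction times are
#' truncated normal (at 0.1 s).
#'
#' @param w_face,w_object,side_bias Policy weights (unitless).
#' @param w_interaction Weight on the face-by-object cue product (unitless;
#'   0 for a purely additive integrator).
#' @param lapse Lapse probability.
#' @param follow_face_prob Mixture-policy probability (only used by the
#'   mixture policy).
#' @param rt_mean,rt_sd Reaction-time distribution (seconds).
#' @param policy `"logistic"`, `"linear"` or `"mixture"`.
#' @param session_sd Standard deviation of session-level jitter (generative
#'   random effects), applied to `w_face`, `w_object` and `side_bias`, and to
#'   `follow_face_prob` (clamped to `[0.01, 0.99]`) for the mixture policy.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(w_face = 1, w_object = 1, side_bias = 0, lapse = 0.02,
                         follow_face_prob = NULL, rt_mean = 0.8, rt_sd = 0.25,
                         policy = c("logistic", "linear", "mixture"),
                         session_sd = 0, w_interaction = 0) {
  policy <- match.arg(policy)
  check_prob(lapse, "lapse")
  if (!is.null(follow_face_prob)) check_prob(follow_face_prob, "follow_face_prob")
  if (rt_sd < 0) stop_param("rt_sd must be >= 0")
  if (session_sd < 0) stop_param("session_sd must be >= 0")
  if (policy == "mixture" && is.null(follow_face_prob)) {
    stop_param("mixture policy requires follow_face_prob")
  }
  structure(list(w_face = w_face, w_object = w_object, side_bias = side_bias,
                 lapse = lapse, follow_face_prob = follow_face_prob,
                 rt_mean = rt_mean, rt_sd = rt_sd, policy = policy,
                 session_sd = session_sd, w_interaction = w_interaction),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent_params> policy=%s w_face=%.3g w_object=%.3g bias=%.3g lapse=%.3g",
              x$policy, x$w_face, x$w_object, x$side_bias, x$lapse))
  if (!is.null(x$follow_face_prob)) cat(sprintf(" follow_face=%.3g", x$follow_face_prob))
  cat("\n")
  invisible(x)
}

#' Simulate agent choices on a schedule
#'
#' Completes a schedule from [make_session_schedule()]: draws a choice per
#' trial from the agent's policy, a reaction time, recomputes cumulative
#' onsets from the realized reaction times, and fills accuracy under the
#' selected convention.
#'
#' The default `"reliable_cue"` accuracy convention scores a trial correct
#' when the choice matches the side indicated by the condition's
#' high-reliability source (face direction in the Face condition, the better
#' object in the Object condition, either cue in the Mixed condition, where
#' both are highly reliable). `"reward"` scores against the realized rewarded
#' side.
#'
#' @param schedule Output of [make_session_schedule()].
#' @param params [agent_params()].
#' @param seed Integer seed.
#' @param accuracy_convention `"reliable_cue"` or `"reward"`.
#' @return The completed trial data.frame.
#' @export
simulate_agent_choices <- function(schedule, params, seed = 1,
                                   accuracy_convention = c("reliable_cue", "reward")) {
  accuracy_convention <- match.arg(accuracy_convention)
  if (!inherits(params, "agent_params")) stop_param("params must be agent_params")
  n <- nrow(schedule)
  if (is.null(n) || n == 0) stop_param("schedule must contain at least one trial")

  old <- .Random.seed_guard(derive_seed(seed, schedule$session_id[1],
                                        schedule$condition[1] %||% "exp1", "choices"))
  on.exit(old(), add = TRUE)

  f <- side_code(schedule$face_direction)
  o <- side_code(schedule$better_object_side)

  # session-level jitter (generative random effects): on the weights for
  # weight-based policies, on the follow probability for the mixture policy
  wf <- params$w_face; wo <- params$w_object; sb <- params$side_bias
  wfo <- params$w_interaction %||% 0
  qf <- params$follow_face_prob
  lapse <- params$lapse
  if (params$session_sd > 0) {
    wf <- wf + stats::rnorm(1, 0, params$session_sd)
    wo <- wo + stats::rnorm(1, 0, params$session_sd)
    sb <- sb + stats::rnorm(1, 0, params$session_sd)
    wfo <- wfo + stats::rnorm(1, 0, params$session_sd)
    if (!is.null(qf)) {
      qf <- min(max(qf + stats::rnorm(1, 0, params$session_sd), 0.01), 0.99)
    }
    if (params$lapse > 0) {
      lapse <- min(max(params$lapse + stats::rnorm(1, 0, params$session_sd), 0), 1)
    }
  }

  p_right <- switch(params$policy,
    logistic = stats::plogis(wf * f + wo * o + wfo * f * o + sb),
    linear = pmin(pmax(0.5 + 0.5 * (wf * f + wo * o + wfo * f * o + sb), 0), 1),
    mixture = {
      follow_face <- stats::runif(n) < qf
      ifelse(follow_face, (f + 1) / 2, (o + 1) / 2)
    })
  lapse_trial <- stats::runif(n) < lapse
  p_right[lapse_trial] <- 0.5
  choice <- ifelse(stats::runif(n) < p_right, "right", "left")
  rt <- rtruncnorm_lower(n, params$rt_mean, params$rt_sd, 0.1)

  out <- schedule
  out$choice <- choice
  out$rt <- rt
  out$onset_decision <- cue_onsets(rt, out$delay, out$iti)
  out$onset_outcome <- out$onset_decision + rt + out$delay
  out$valid <- rt <= 10
  out$accuracy <- score_accuracy(out, accuracy_convention)
  attr(out, "agent_params") <- params
  attr(out, "session_weights") <- c(w_face = wf, w_object = wo, side_bias = sb)
  out
}

score_accuracy <- function(trials, convention) {
  responded <- trials$choice != "none"
  acc <- rep(NA_integer_, nrow(trials))
  if (convention == "reward") {
    acc[responded] <- as.integer(trials$choice[responded] ==
                                   trials$rewarded_side[responded])
    return(acc)
  }
  correct <- ifelse(trials$condition == "Face",
                    trials$choice == trials$face_direction,
                    ifelse(trials$condition == "Object",
                           trials$choice == trials$better_object_side,
                           trials$choice == trials$face_direction |
                             trials$choice == trials$better_object_side))
  acc[responded] <- as.integer(correct[responded])
  acc
}

#' Perturb an agent as a stimulation stand-in
#'
#' Models offline transcranial ultrasound stimulation of a site as a
#' down-weighting of the corresponding cue channel: `mSTS` scales the face
#' weight only (social information), `EVC` the object weight only, `dmFPC`
#' the weight of whichever cue is reliable in the given condition (so its
#' disruption impairs both Face and Object conditions), and `sham` is the
#' identity. For mixture agents the perturbed channel loses a fraction
#' `1 - factor` of its deliberate follows to random guessing (half of which
#' land on each side), so degrading a channel the agent rarely uses barely
#' moves its behavior.
#'
#' @param params [agent_params()].
#' @param site `"sham"`, `"dmFPC"`, `"mSTS"` or `"EVC"`.
#' @param condition Condition the perturbed agent will play (needed for the
#'   reliability-dependent `dmFPC` rule).
#' @param factor Multiplicative down-weighting factor in `[0, 1)`.
#' @return Modified `agent_params` with a `tus` attribute recording the
#'   mapping applied.
#' @export
apply_tus_perturbation <- function(params, site, condition = "Face", factor = 0.6) {
  site <- match.arg(site, c("sham", "dmFPC", "mSTS", "EVC"))
  condition <- match.arg(condition, c("Face", "Object", "Mixed"))
  if (!is.numeric(factor) || factor < 0 || factor >= 1) {
    stop_param("factor must be in [0, 1)")
  }
  out <- params
  if (site == "sham") {
    attr(out, "tus") <- list(site = site, factor = 1)
    return(out)
  }
  reliable_cue <- if (condition == "Object") "object" else "face"
  target <- switch(site,
    dmFPC = reliable_cue,
    mSTS = "face",
    EVC = "object")
  if (params$policy == "mixture") {
    # degrading a channel converts a fraction (1 - factor) of that channel's
    # deliberate follows into guesses, half of which land on each side
    q <- params$follow_face_prob
    if (target == "face") {
      out$follow_face_prob <- q * (1 + factor) / 2
    } else {
      out$follow_face_prob <- q + (1 - q) * (1 - factor) / 2
    }
  } else if (target == "face") {
    out$w_face <- params$w_face * factor
  } else {
    out$w_object <- params$w_object * factor
  }
  attr(out, "tus") <- list(site = site, condition = condition,
                           target = target, factor = factor)
  out
}

#' Simulate a multi-session experiment
#'
#' Convenience wrapper generating `n_sessions` completed sessions of one or
#' more conditions, row-bound into one trial table. Per-session random
#' streams are derived from `(seed, session_id)`.
#'
#' @param n_sessions Number of sessions.
#' @param conditions Conditions played (each as one block per session).
#' @param params [agent_params()] (shared across sessions; session-level
#'   weight jitter comes from `params$session_sd`).
#' @param n_trials Trials per condition block.
#' @param seed Top-level seed.
#' @param tus_site Optional stimulation site; the perturbation is applied per
#'   condition via [apply_tus_perturbation()].
#' @param tus_factor Down-weighting factor passed on.
#' @param session_prefix Prefix for generated session ids.
#' @param experiment `"exp2"` or `"exp3"` timing.
#' @param accuracy_convention Passed to [simulate_agent_choices()].
#' @return Combined trial data.frame.
#' @export
simulate_experiment <- function(n_sessions, conditions = c("Face", "Object", "Mixed"),
                                params = agent_params(), n_trials = 50, seed = 1,
                                tus_site = "sham", tus_factor = 0.6,
                                session_prefix = "s",
                                experiment = c("exp2", "exp3"),
                                accuracy_convention = "reliable_cue") {
  experiment <- match.arg(experiment)
  out <- vector("list", n_sessions * length(conditions))
  k <- 0
  for (i in seq_len(n_sessions)) {
    sid <- sprintf("%s%03d", session_prefix, i)
    for (cond in conditions) {
      k <- k + 1
      p <- apply_tus_perturbation(params, tus_site, cond, tus_factor)
      sched <- make_session_schedule(cond, n_trials = n_trials,
                                     seed = seed, session_id = sid,
                                     tus_site = tus_site,
                                     experiment = experiment)
      out[[k]] <- simulate_agent_choices(sched, p, seed = seed,
                                         accuracy_convention = accuracy_convention)
    }
  }
  do.call(rbind, out)
}

#' Generate a repetition-suppression session schedule
#'
#' Two faces are shown in succession; the design crosses direction repetition
#' with identity repetition in equal cell counts. A directed first face is
#' always followed by the same direction (so direction repeats); a neutral
#' first face is followed by a left/right second face in balance (direction
#' does not repeat). Identities are drawn from a set of `n_identities` faces.
#' Responses (side of the second face), reaction times, correctness and event
#' onsets are simulated so the schedule can feed design-matrix construction.
#'
#' @param n_trials Number of trials, divisible by 4 (140 is one session).
#' @param n_identities Number of face identities (>= 2).
#' @param seed Integer seed.
#' @param session_id Session identifier.
#' @param p_correct Probability of a correct response per trial.
#' @param rt_mean,rt_sd Reaction-time distribution (s).
#' @param rt_invalid_threshold Responses slower than this are invalid
#'   (per-animal: 1.5 s or 2.5 s).
#' @return Data.frame of two-face trials with repetition labels and onsets.
#' @export
make_exp1_schedule <- function(n_trials = 140, n_identities = 5, seed = 1,
                               session_id = "e1s01", p_correct = 0.95,
                               rt_mean = 0.7, rt_sd = 0.2,
                               rt_invalid_threshold = 1.5) {
  if (n_trials %% 4 != 0) stop_param("n_trials must be divisible by 4")
  if (n_identities < 2) stop_param("n_identities must be >= 2")
  old <- .Random.seed_guard(derive_seed(seed, session_id, "exp1"))
  on.exit(old(), add = TRUE)

  per_cell <- n_trials / 4
  cells <- expand.grid(direction_repeat = c(TRUE, FALSE),
                       identity_repeat = c(TRUE, FALSE))
  cells <- cells[rep(seq_len(4), each = per_cell), ]
  cells <- cells[sample.int(n_trials), ]

  second_face <- sample(c("left", "right"), n_trials, replace = TRUE)
  first_face <- ifelse(cells$direction_repeat, second_face, "neutral")
  second_identity <- sprintf("id%02d", sample.int(n_identities, n_trials, replace = TRUE))
  first_identity <- ifelse(cells$identity_repeat, second_identity,
                           vapply(second_identity, function(id) {
                             pool <- setdiff(sprintf("id%02d", seq_len(n_identities)), id)
                             pool[sample.int(length(pool), 1)]
                           }, character(1)))

  rt <- rtruncnorm_lower(n_trials, rt_mean, rt_sd, 0.1)
  correct <- stats::runif(n_trials) < p_correct
  responded <- stats::runif(n_trials) > 0.02
  valid <- responded & rt <= rt_invalid_threshold
  response_side <- ifelse(correct, second_face, other_side(second_face))
  response_side[!responded] <- "none"

  # trial layout: first face 0.5 s, blank 0.5 s, second face (decision onset),
  # response within 3 s, outcome, ITI 3-4 s
  iti <- stats::runif(n_trials, 3, 4)
  trial_len <- 0.5 + 0.5 + pmin(rt, 3) + 0.5 + iti
  starts <- c(0, cumsum(trial_len))[seq_len(n_trials)]
  onset_first_face <- starts
  onset_decision <- starts + 1.0
  onset_outcome <- onset_decision + pmin(rt, 3) + 0.2

  data.frame(
    session_id = session_id,
    trial_index = seq_len(n_trials) - 1L,
    first_face = first_face,
    first_identity = first_identity,
    second_face = second_face,
    second_identity = second_identity,
    direction_repeat = cells$direction_repeat,
    identity_repeat = cells$identity_repeat,
    correct = correct,
    response_side = response_side,
    rt = rt,
    valid = valid,
    rewarded = correct & responded,
    onset_first_face = onset_first_face,
    onset_decision = onset_decision,
    onset_outcome = onset_outcome,
    stringsAsFactors = FALSE
  )
}
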