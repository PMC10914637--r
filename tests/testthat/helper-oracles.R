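# Independent brute-force oracles used to cross-check package implementations.
# These are written from the textbook definitions and never call the package
# functions they validate.

# Holm step-down adjustment, literal definition.
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_max <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[o[i]])
    running_max <- max(running_max, val)
    adj[o[i]] <- running_max
  }
  adj
}

# Benjamini-Hochberg adjusted p-values, literal step-up definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running_min <- 1
  ranks <- rank(p, ties.method = "first")
  for (idx in o) {
    val <- min(1, m * p[idx] / ranks[idx])
    running_min <- min(running_min, val)
    adj[idx] <- running_min
  }
  adj
}

# Direct-summation convolution of boxcar events with a kernel, evaluated at
# arbitrary sample times: out(t) = sum_i amp_i * dt * sum_{u in boxcar_i} k(t - u).
brute_convolved_regressor <- function(onsets, durations, amplitudes,
                                      kernel, dt, sample_times) {
  ktime <- attr(kernel, "time")
  n_fine <- max(round(sample_times[length(sample_times)] / dt) + 1,
                round((max(onsets + durations) + 30) / dt))
  x <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- min(ceiling((onsets[i] + durations[i]) / dt), n_fine)
    x[a:b] <- x[a:b] + amplitudes[i]
  }
  vapply(sample_times, function(t0) {
    j0 <- round(t0 / dt) + 1
    acc <- 0
    for (u in seq_len(min(j0, length(kernel)))) {
      acc <- acc + x[j0 - u + 1] * kernel[u]
    }
    acc * dt
  }, numeric(1))
}

# Per-timepoint regression via stats::lm, one call per timepoint.
brute_beta_timecourse <- function(epochs, trialtype, rt = NULL) {
  Y <- unclass(epochs)
  out <- matrix(NA_real_, if (is.null(rt)) 2 else 3, ncol(Y))
  for (j in seq_len(ncol(Y))) {
    d <- data.frame(y = Y[, j], trialtype = trialtype)
    f <- y ~ trialtype
    if (!is.null(rt)) {
      d$rt <- (rt - mean(rt)) / sd(rt)
      f <- y ~ trialtype + rt
    }
    out[, j] <- coef(lm(f, data = d))
  }
  out
}

# Accuracy of a mixture agent scored against the condition-reliable cue,
# trial by trial.
brute_mixture_accuracy <- function(trials, followed_face) {
  reliable <- ifelse(trials$condition == "Object",
                     trials$better_object_side, trials$face_direction)
  chosen <- ifelse(followed_face, trials$face_direction, trials$better_object_side)
  as.integer(chosen == reliable)
}

# Small completed dataset shared across behavioral tests.
make_behavior_data <- function(n_sessions = 6, condition = "Face",
                               params = agent_params(w_face = 0.6, w_object = 0.2,
                                                     policy = "linear", lapse = 0,
                                                     session_sd = 0.1),
                               n_trials = 50, seed = 42, tus_site = "sham") {
  simulate_experiment(n_sessions, condition, params, n_trials = n_trials,
                      seed = seed, tus_site = tus_site)
}
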