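sim_session <- function(seed = 5, n_trials = 40, condition = "Face") {
  s <- make_session_schedule(condition, n_trials, seed = seed)
  simulate_agent_choices(s, agent_params(), seed = seed)
}

test_that("the full gaze-task regressor set builds with confounds appended", {
  trials <- sim_session(seed = 12, n_trials = 50)
  # force one no-response and one invalid slow trial so every registered
  # regressor has events
  trials$choice[3] <- "none"; trials$accuracy[3] <- NA
  trials$rt[7] <- 11; trials$valid[7] <- FALSE
  trials$rt[9] <- 12; trials$valid[9] <- FALSE
  n_tp <- 400
  conf <- matrix(rnorm(n_tp * 13), n_tp, 13)
  des <- build_design(trials, "GLM3", confounds = conf, tr = 1.48,
                      n_timepoints = n_tp)
  expect_equal(ncol(des$X), 14 + 13)
  expect_equal(sum(!des$convolved_mask), 3 + 13)  # 3 spike columns + confounds
  expect_length(des$dropped, 0)
  expect_equal(nrow(des$X), n_tp)
})

test_that("empty registered regressors are dropped with a warning", {
  e1 <- make_exp1_schedule(40, seed = 6)
  e1$valid <- TRUE  # no invalid trials in this session
  expect_warning(des <- build_design(e1, "GLM1", tr = 1.48, n_timepoints = 300),
                 "fchInvalid")
  expect_false(any(c("fchInvalid", "schInvalid") %in% des$column_names))
  expect_true(all(c("face", "dsimFace", "simFace", "RT") %in% des$column_names))
})

test_that("identity-repetition variant swaps the repetition regressors", {
  e1 <- make_exp1_schedule(40, seed = 6)
  des <- suppressWarnings(build_design(e1, "GLM2", tr = 1.48, n_timepoints = 300))
  expect_true(all(c("dsimIdentity", "simIdentity") %in% des$column_names))
  expect_false("dsimFace" %in% des$column_names)
})

test_that("convolved columns match the direct-summation oracle", {
  tr <- 1.48; n_tp <- 80; dt <- tr / 10
  kernel <- hrf_kernel(dt)
  sample_times <- ((seq_len(n_tp) - 1) + 0.5) * tr
  # single 1 s event at t = 0 plus a random event table
  cases <- list(
    list(onset = 0, duration = 1, amplitude = 1),
    list(onset = c(3.7, 20.2, 41.9, 42.4), duration = c(1, 0.5, 2, 1),
         amplitude = c(1, -0.6, 2, 0.3))
  )
  for (cs in cases) {
    ev <- data.frame(name = "congruent", onset = cs$onset,
                     duration = cs$duration, amplitude = cs$amplitude,
                     convolve = TRUE)
    des <- suppressWarnings(build_design(ev, "GLM3", tr = tr,
                                         n_timepoints = n_tp))
    oracle <- brute_convolved_regressor(cs$onset, cs$duration, cs$amplitude,
                                        kernel, dt, sample_times)
    expect_lt(max(abs(des$X[, "congruent"] - oracle)), 1e-10)
  }
})

test_that("unknown regressor names and bad events are rejected", {
  ev <- data.frame(name = "mystery", onset = 1, duration = 1, amplitude = 1,
                   convolve = TRUE)
  expect_error(build_design(ev, "GLM3", tr = 1.48, n_timepoints = 50), "registry")
  ev2 <- data.frame(name = "congruent", onset = -2, duration = 1,
                    amplitude = 1, convolve = TRUE)
  expect_error(build_design(ev2, "GLM3", tr = 1.48, n_timepoints = 50), ">= 0")
})

test_that("high-pass filtering removes slow and keeps fast fluctuations", {
  tr <- 1.48; n <- 500; t <- (0:(n - 1)) * tr
  retained <- function(period) {
    y <- sin(2 * pi * t / period)
    f <- highpass_filter(y, tr, 100)
    i <- 100:400  # interior, away from edges
    sd(f[i]) / sd(y[i])
  }
  expect_lt(retained(200), 0.5)
  expect_gt(retained(20), 0.9)
  const <- highpass_filter(rep(7, n), tr, 100)
  expect_lt(max(abs(const)), 1e-10)
  expect_warning(highpass_filter(rnorm(20), 1.48, 100), "skipped")
  expect_error(highpass_filter(rnorm(50), 1.48, 2), "cutoff")
})

test_that("noiseless construction is recovered exactly by least squares", {
  trials <- sim_session(seed = 3)
  n_tp <- 350
  des <- suppressWarnings(build_design(trials, "GLM3", tr = 1.48,
                                       n_timepoints = n_tp))
  beta_true <- seq_len(ncol(des$X)) / 10
  y <- 2 + as.numeric(des$X %*% beta_true)
  fit <- fit_glm(y, des)
  expect_lt(max(abs(fit$betas[-1] - beta_true)), 1e-8)
  expect_equal(unname(fit$betas[1]), 2, tolerance = 1e-8)
  expect_equal(fit$dof, n_tp - ncol(des$X) - 1)
  expect_lt(fit$sigma2, 1e-16)
})

test_that("rank-deficient designs fail loudly naming the columns", {
  trials <- sim_session(seed = 3)
  des <- suppressWarnings(build_design(trials, "GLM3", tr = 1.48,
                                       n_timepoints = 350))
  dup <- des
  dup$X <- cbind(des$X, clone = des$X[, "congruent"])
  expect_error(fit_glm(rnorm(350), dup), "clone")
})

test_that("contrasts are insensitive to drift the filter removes", {
  trials <- sim_session(seed = 8)
  eff <- ground_truth_effects(amp_congruent = 0.5, amp_incongruent = 1.2,
                              amp_rt = 0, noise_sd = 0, drift_amp = 0,
                              baseline = 0, confound_mix = 0)
  ts <- simulate_roi_bold(trials, eff, seed = 8)
  n_tp <- length(ts$values)
  t_sec <- (seq_len(n_tp) - 1) * ts$tr
  drifted <- ts$values + cos(2 * pi * t_sec / 600)
  des <- suppressWarnings(build_design(trials, "GLM3", tr = ts$tr,
                                       n_timepoints = n_tp))
  des_f <- highpass_design(des)
  fit_clean <- fit_glm(highpass_filter(ts$values, ts$tr), des_f)
  fit_drift <- fit_glm(highpass_filter(drifted, ts$tr), des_f)
  con <- fit_clean$betas[["congruent"]] - fit_drift$betas[["congruent"]]
  expect_lt(abs(con), 0.05)
})

test_that("group contrasts treat sessions as the random-effects unit", {
  fits <- lapply(1:6, function(i) {
    trials <- sim_session(seed = 20 + i)
    eff <- ground_truth_effects(amp_congruent = 0.4, amp_incongruent = 1.0,
                                amp_rt = 0.1, noise_sd = 0.3, drift_amp = 0,
                                baseline = 10, confound_mix = 0)
    ts <- simulate_roi_bold(trials, eff, seed = 20 + i)
    des <- suppressWarnings(build_design(trials, "GLM3", tr = ts$tr,
                                         n_timepoints = length(ts$values)))
    fit_glm(ts, des)
  })
  grp <- contrast_group(fits, c(congruent = 1))
  expect_lt(abs(grp$estimate - 0.4), 0.2)
  expect_false(grp$degenerate)
  expect_equal(grp$df, 5)
  # degenerate variance path: identical per-session values
  same <- contrast_group(fits[c(1, 1, 1)], c(congruent = 1))
  expect_true(same$degenerate)
  expect_true(is.na(same$p))
  expect_error(contrast_group(fits[1:2], c(congruent = 1)), ">= 3")
  expect_error(contrast_group(fits, c(1)), "named")
  expect_error(contrast_group(fits, c(nonexistent = 1)), "absent")
})
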