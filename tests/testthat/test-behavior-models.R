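test_that("a perfect face predictor yields unit face slope exactly", {
  trials <- make_behavior_data(4, seed = 1)
  trials$choice <- trials$face_direction  # deterministic follower
  fit <- suppressWarnings(fit_choice_model(trials, "Face"))
  ct <- coef_table(fit)
  expect_equal(ct$estimate[ct$term == "facedirection"], 1, tolerance = 1e-10)
  expect_equal(ct$estimate[ct$term == "objectdirection"], 0, tolerance = 1e-10)
  expect_equal(ct$estimate[ct$term == "facedirection:objectdirection"], 0,
               tolerance = 1e-10)
})

test_that("choice-model estimates match generative linear-policy weights", {
  trials <- make_behavior_data(12, seed = 31)
  fit <- fit_choice_model(trials, "Face")
  ct <- coef_table(fit)
  face <- ct[ct$term == "facedirection", ]
  obj <- ct[ct$term == "objectdirection", ]
  expect_gt(face$ci_high, 0.6 - 0.12); expect_lt(face$ci_low, 0.6 + 0.12)
  expect_gt(obj$ci_high, 0.2 - 0.12); expect_lt(obj$ci_low, 0.2 + 0.12)
  expect_true(all(ct$ci_high >= ct$ci_low))
  expect_true(all(ct$p >= 0 & ct$p <= 1))
})

test_that("slopes flip sign but keep magnitude under a left/right relabel", {
  trials <- make_behavior_data(6, seed = 8)
  flip <- function(x) ifelse(x == "left", "right", "left")
  mirrored <- trials
  for (col in c("face_direction", "better_object_side", "rewarded_side", "choice")) {
    mirrored[[col]] <- flip(mirrored[[col]])
  }
  a <- coef_table(fit_choice_model(trials, "Face"))
  b <- coef_table(fit_choice_model(mirrored, "Face"))
  for (tm in c("facedirection", "objectdirection")) {
    expect_equal(b$estimate[b$term == tm], a$estimate[a$term == tm],
                 tolerance = 1e-6)
  }
  # interaction of two flipped regressors is unchanged; intercept flips
  expect_equal(b$estimate[b$term == "(Intercept)"],
               -a$estimate[a$term == "(Intercept)"], tolerance = 1e-6)
})

test_that("estimates are invariant to session ordering", {
  trials <- make_behavior_data(6, seed = 15)
  shuffled <- trials[rev(seq_len(nrow(trials))), ]
  a <- coef_table(fit_choice_model(trials, "Face"))
  b <- coef_table(fit_choice_model(shuffled, "Face"))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-6)
})

test_that("single-session data falls back to fixed effects with a warning", {
  trials <- make_behavior_data(1, seed = 3)
  expect_warning(fit <- fit_choice_model(trials, "Face"), "single session")
  expect_true(fit$fell_back_to_fixed)
  ols <- lm(I(ifelse(choice == "right", 1, -1)) ~
              I(ifelse(face_direction == "right", 1, -1)) *
              I(ifelse(better_object_side == "right", 1, -1)), data = trials)
  expect_equal(sort(coef_table(fit)$estimate), sort(unname(coef(ols))),
               tolerance = 1e-10)
})

test_that("incongruency cost equals q - 1 for a mixture agent", {
  params <- agent_params(follow_face_prob = 0.8, lapse = 0, policy = "mixture",
                         session_sd = 0.04)
  trials <- simulate_experiment(10, "Face", params, n_trials = 120, seed = 77)
  fit <- fit_accuracy_congruency_model(trials)
  b2 <- coef_table(fit)[coef_table(fit)$term == "incongruency", ]
  expect_lt(abs(b2$estimate - (-0.2)), 0.08)
  # a perfect agent has zero incongruency effect, exactly
  perfect <- trials
  perfect$accuracy <- 1L
  fit0 <- suppressWarnings(fit_accuracy_congruency_model(perfect))
  expect_equal(coef_table(fit0)$estimate[2], 0, tolerance = 1e-12)
  # all-congruent data is rank deficient
  expect_error(fit_accuracy_congruency_model(trials[trials$congruent, ]),
               "constant")
})

test_that("stimulation-versus-sham accuracy contrast recovers the follow-rate gap", {
  sham <- simulate_experiment(6, "Face",
                              agent_params(follow_face_prob = 0.9, lapse = 0,
                                           policy = "mixture", session_sd = 0.03),
                              n_trials = 100, seed = 51)
  tus <- simulate_experiment(6, "Face",
                             agent_params(follow_face_prob = 0.75, lapse = 0,
                                          policy = "mixture", session_sd = 0.03),
                             n_trials = 100, seed = 52, session_prefix = "t")
  tus$tus_site <- "dmFPC"
  fit <- fit_tus_accuracy_model(rbind(sham, tus), "dmFPC", "incongruent")
  b2 <- coef_table(fit)[coef_table(fit)$term == "roi", ]
  expect_lt(abs(b2$estimate - (-0.15)), 0.1)
  expect_lt(b2$ci_low, -0.15); expect_gt(b2$ci_high, -0.15)
  # interaction form includes the congruency terms
  fit_int <- fit_tus_accuracy_model(rbind(sham, tus), "dmFPC",
                                    with_interaction = TRUE)
  expect_true("roi:incongruency" %in% coef_table(fit_int)$term)
  expect_error(fit_tus_accuracy_model(tus, "dmFPC"), "sham")
})

test_that("stimulation-by-cue interaction recovers a halved face weight", {
  base <- agent_params(w_face = 0.6, w_object = 0.2, policy = "linear",
                       lapse = 0, session_sd = 0.05)
  sham <- simulate_experiment(8, "Face", base, n_trials = 100, seed = 61)
  tus <- simulate_experiment(8, "Face", base, n_trials = 100, seed = 62,
                             tus_site = "mSTS", tus_factor = 0.5,
                             session_prefix = "t")
  fit <- fit_tus_choice_model(rbind(sham, tus), "mSTS", "face")
  ct <- coef_table(fit)
  b4 <- ct[ct$term == "cuedirection:roi", ]
  expect_lt(b4$ci_low, -0.3); expect_gt(b4$ci_high, -0.3)
  # null: identical agents -> interaction near zero
  tus0 <- simulate_experiment(8, "Face", base, n_trials = 100, seed = 63,
                              session_prefix = "u")
  tus0$tus_site <- "mSTS"
  fit0 <- fit_tus_choice_model(rbind(sham, tus0), "mSTS", "face")
  b40 <- coef_table(fit0)[coef_table(fit0)$term == "cuedirection:roi", ]
  expect_lt(b40$ci_low, 0); expect_gt(b40$ci_high, 0)
})

test_that("diagnostics annotate normality and likelihood-ratio comparisons", {
  trials <- make_behavior_data(10, seed = 19,
                               params = agent_params(w_face = 0.5, w_object = 0.2,
                                                     policy = "linear", lapse = 0,
                                                     session_sd = 0.25),
                               n_trials = 80)
  full <- fit_choice_model(trials, "Face")
  d <- data.frame(session_id = factor(trials$session_id),
                  choice = side_code(trials$choice),
                  facedirection = side_code(trials$face_direction))
  reduced <- socialcue:::fit_mixed(~ facedirection, d, link = "linear",
                                   response = "choice")
  expect_false(full$fell_back_to_fixed)
  expect_false(reduced$fell_back_to_fixed)
  out <- check_model_diagnostics(full, reduced)
  expect_true(is.finite(out$ks_p) && out$ks_p >= 0 && out$ks_p <= 1)
  expect_gte(out$lr_test$statistic, 0)   # full fit never below nested fit
  expect_gt(out$lr_test$df, 0)
  expect_error(check_model_diagnostics(reduced, full), "nested")
})

test_that("degenerate random effects trigger the all-fixed fallback", {
  trials <- make_behavior_data(4, seed = 23,
                               params = agent_params(w_face = 0.5, w_object = 0.2,
                                                     policy = "linear", lapse = 0,
                                                     session_sd = 0))
  # no true session variance: the boundary fit is flagged and refit all-fixed
  fit <- fit_choice_model(trials, "Face")
  if (fit$fell_back_to_fixed) {
    expect_false(fit$hessian_pd)
    ols <- lm(I(ifelse(choice == "right", 1, -1)) ~
                I(side_code(face_direction)) * I(side_code(better_object_side)),
              data = trials)
    expect_equal(sort(coef_table(fit)$estimate), sort(unname(coef(ols))),
                 tolerance = 1e-10)
  } else {
    succeed("random-effects fit stayed positive definite on this draw")
  }
})

test_that("the logistic link recovers logistic generative weights", {
  params <- agent_params(w_face = 1.2, w_object = 0.4, policy = "logistic",
                         lapse = 0, session_sd = 0.1)
  trials <- simulate_experiment(8, "Face", params, n_trials = 150, seed = 91)
  fit <- fit_choice_model(trials, "Face", link = "logistic")
  ct <- coef_table(fit)
  face <- ct[ct$term == "facedirection", ]
  expect_lt(abs(face$estimate - 1.2), 0.45)
  expect_equal(fit$link, "logistic")
})
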