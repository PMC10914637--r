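test_that("schedules realize the nominal cue reliabilities", {
  n_sessions <- 30
  trials <- do.call(rbind, lapply(seq_len(n_sessions), function(i) {
    make_session_schedule("Face", 50, seed = 7, session_id = sprintf("s%02d", i))
  }))
  n <- nrow(trials)
  p_face_hat <- mean(trials$face_direction == trials$rewarded_side)
  p_obj_hat <- mean(trials$rewarded_side == trials$better_object_side)
  ci_face <- qbinom(c(0.005, 0.995), n, 0.9) / n
  ci_obj <- qbinom(c(0.005, 0.995), n, 0.6) / n
  expect_gte(p_face_hat, ci_face[1]); expect_lte(p_face_hat, ci_face[2])
  expect_gte(p_obj_hat, ci_obj[1]); expect_lte(p_obj_hat, ci_obj[2])
})

test_that("degenerate reliabilities make every trial congruent", {
  s <- make_session_schedule("Mixed", 40, reliabilities = c(1, 1), seed = 2)
  expect_true(all(s$congruent))
  expect_true(all(s$face_direction == s$rewarded_side))
  expect_true(all(s$rewarded_side == s$better_object_side))
})

test_that("congruency labeling is deterministic and mirror-invariant", {
  sides <- expand.grid(face = c("left", "right"), better = c("left", "right"),
                       stringsAsFactors = FALSE)
  trials <- data.frame(face_direction = sides$face,
                       better_object_side = sides$better)
  lab <- label_congruency(trials)
  expect_equal(lab, sides$face == sides$better)
  mirrored <- data.frame(
    face_direction = ifelse(sides$face == "left", "right", "left"),
    better_object_side = ifelse(sides$better == "left", "right", "left"))
  expect_identical(label_congruency(mirrored), lab)
  expect_identical(label_congruency(trials), lab)
  expect_error(label_congruency(data.frame(face_direction = NA,
                                           better_object_side = "left")),
               "must be set")
})

test_that("trial invariants hold on simulated sessions", {
  s <- make_session_schedule("Object", 50, seed = 9)
  t <- simulate_agent_choices(s, agent_params(), seed = 9)
  expect_true(all(t$onset_outcome > t$onset_decision))
  expect_true(all(t$onset_decision >= 0))
  expect_true(all(diff(t$onset_decision) > 0))
  expect_true(all(t$accuracy[t$choice != "none"] %in% 0:1))
  expect_identical(t$congruent, t$face_direction == t$better_object_side)
})

test_that("schedules and choices are bit-reproducible from the seed", {
  a <- simulate_agent_choices(make_session_schedule("Face", 30, seed = 5),
                              agent_params(), seed = 5)
  b <- simulate_agent_choices(make_session_schedule("Face", 30, seed = 5),
                              agent_params(), seed = 5)
  expect_identical(a, b)
  c2 <- simulate_agent_choices(make_session_schedule("Face", 30, seed = 6),
                               agent_params(), seed = 6)
  expect_false(identical(a$choice, c2$choice))
})

test_that("mixture-agent accuracy matches the per-trial oracle", {
  q <- 0.7
  s <- make_session_schedule("Face", 2000, seed = 11)
  params <- agent_params(follow_face_prob = q, lapse = 0, policy = "mixture")
  t <- simulate_agent_choices(s, params, seed = 11)
  # reconstruct which cue was followed from the realized choice
  followed_face_like <- t$choice == t$face_direction
  oracle <- brute_mixture_accuracy(t, followed_face_like)
  expect_identical(t$accuracy, oracle)
  expect_true(all(t$accuracy[t$congruent] == 1))
  inc_acc <- mean(t$accuracy[!t$congruent])
  n_inc <- sum(!t$congruent)
  expect_lt(abs(inc_acc - q), 3 * sqrt(q * (1 - q) / n_inc))
})

test_that("an uninformative agent performs at chance", {
  s <- make_session_schedule("Face", 2000, seed = 4)
  t <- simulate_agent_choices(s, agent_params(w_face = 0, w_object = 0,
                                              lapse = 0), seed = 4)
  expect_lt(abs(mean(t$choice == "right") - 0.5), 0.04)
})

test_that("a pure face-follower earns reward at the face reliability", {
  s <- make_session_schedule("Face", 4000, seed = 13)
  t <- simulate_agent_choices(s, agent_params(w_face = 50, w_object = 0,
                                              lapse = 0),
                              seed = 13, accuracy_convention = "reward")
  expect_lt(abs(mean(t$accuracy) - 0.9), 0.02)
})

test_that("stimulation perturbations follow the site mapping", {
  p <- agent_params(w_face = 0.8, w_object = 0.5)
  expect_identical(unclass(apply_tus_perturbation(p, "sham"))[1:8],
                   unclass(p)[1:8])
  msts <- apply_tus_perturbation(p, "mSTS", "Object", factor = 0.5)
  expect_equal(msts$w_face, 0.4)
  expect_equal(msts$w_object, 0.5)
  evc <- apply_tus_perturbation(p, "EVC", "Face", factor = 0.5)
  expect_equal(evc$w_object, 0.25)
  expect_equal(evc$w_face, 0.8)
  fpc_face <- apply_tus_perturbation(p, "dmFPC", "Face", factor = 0.5)
  fpc_obj <- apply_tus_perturbation(p, "dmFPC", "Object", factor = 0.5)
  expect_equal(fpc_face$w_face, 0.4)
  expect_equal(fpc_obj$w_object, 0.25)
  expect_error(apply_tus_perturbation(p, "amygdala"), "arg")
})

test_that("frontopolar perturbation hurts incongruent trials in both conditions", {
  acc_drop <- sapply(c("Face", "Object"), function(cond) {
    # the trained agent follows whichever cue is reliable in the condition
    q <- if (cond == "Face") 0.9 else 0.1
    base <- agent_params(follow_face_prob = q, lapse = 0, policy = "mixture")
    sham <- simulate_experiment(6, cond, base, n_trials = 200, seed = 21)
    tus <- simulate_experiment(6, cond, base, n_trials = 200, seed = 22,
                               tus_site = "dmFPC", tus_factor = 0.5)
    c(incong = mean(sham$accuracy[!sham$congruent]) -
        mean(tus$accuracy[!tus$congruent]),
      cong = mean(sham$accuracy[sham$congruent]) -
        mean(tus$accuracy[tus$congruent]))
  })
  expect_gt(acc_drop["incong", "Face"], 0.1)
  expect_gt(acc_drop["incong", "Object"], 0.1)
  expect_lt(abs(acc_drop["cong", "Face"]), 0.02)
  expect_lt(abs(acc_drop["cong", "Object"]), 0.02)
})

test_that("two-face schedules are balanced and direction-consistent", {
  s <- make_exp1_schedule(140, seed = 3)
  cells <- table(s$direction_repeat, s$identity_repeat)
  expect_true(all(cells == 35))
  directed <- s$first_face != "neutral"
  expect_true(all(s$first_face[directed] == s$second_face[directed]))
  expect_true(all(s$direction_repeat[directed]))
  expect_true(all(!s$direction_repeat[!directed]))
  s4 <- make_exp1_schedule(4, seed = 3)
  expect_true(all(table(s4$direction_repeat, s4$identity_repeat) == 1))
  expect_error(make_exp1_schedule(50), "divisible by 4")
  expect_error(make_exp1_schedule(8, n_identities = 1), "n_identities")
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(make_session_schedule("Face", 0), "n_trials")
  expect_error(make_session_schedule("Face", 10, reliabilities = c(1.2, 0.5)),
               "probability")
  expect_error(agent_params(lapse = 2), "probability")
  expect_error(agent_params(rt_sd = -1), "rt_sd")
  expect_error(agent_params(policy = "mixture"), "follow_face_prob")
  expect_error(simulate_agent_choices(
    make_session_schedule("Face", 5)[0, ], agent_params()), "at least one")
})
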