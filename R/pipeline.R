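#' Run configuration for the end-to-end pipeline
#'
#' @param seed Top-level integer seed; all stage streams derive from it.
#' @param n_sessions Sessions to simulate.
#' @param n_trials Trials per condition block.
#' @param conditions Conditions played per session.
#' @param agent [agent_params()] for the simulated animal.
#' @param effects [ground_truth_effects()] injected into the BOLD simulator.
#' @param tr Repetition time in seconds.
#' @param n_perm Permutations for time-course inference (>= 100).
#' @param window Test window in seconds.
#' @param accuracy_convention `"reliable_cue"` or `"reward"`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n_sessions = 8, n_trials = 50,
                       conditions = c("Face", "Object"),
                       agent = agent_params(w_face = 0.6, w_object = 0.3,
                                            policy = "linear", session_sd = 0.05),
                       effects = ground_truth_effects(),
                       tr = 1.48, n_perm = 200, window = 3,
                       accuracy_convention = "reliable_cue") {
  if (n_perm < 100) stop_param("n_perm must be >= 100")
  if (tr <= 0) stop_param("tr must be positive")
  structure(list(seed = seed, n_sessions = n_sessions, n_trials = n_trials,
                 conditions = conditions, agent = agent, effects = effects,
                 tr = tr, n_perm = n_perm, window = window,
                 accuracy_convention = accuracy_convention),
            class = "run_config")
}

#' Run the simulation-to-inference pipeline
#'
#' Chains the stages: `simulate` (task schedules, agent choices, ROI BOLD;
#' writes per-session events TSVs and series matrices), `behavior` (choice
#' and accuracy mixed models; writes a coefficient table), `glm`
#' (design construction, high-pass, per-session fits, group contrast),
#' `timecourse` (epoching and permutation inference), and `report`
#' (condition-by-term coefficient table). Each stage either completes and
#' writes its outputs or fails; a JSON manifest records the seed, parameter
#' digest and md5 of every file written so a run can be reproduced and
#' verified bit-for-bit.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("simulate", "behavior", "glm", "timecourse",
#'   "report")`, executed in canonical order.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, stages = c("simulate", "behavior", "glm",
                                            "timecourse", "report"),
                         out_dir = "socialcue_run") {
  all_stages <- c("simulate", "behavior", "glm", "timecourse", "report")
  stages <- all_stages[all_stages %in% match.arg(stages, all_stages, several.ok = TRUE)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   parameters = utils::capture.output(utils::str(unclass(config))),
                   stages = stages, files = list())
  note <- function(path) {
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
    path
  }
  log_stage <- function(stage, detail) {
    message(sprintf("[socialcue] stage=%s seed=%d %s", stage, config$seed, detail))
  }

  trials_path <- file.path(out_dir, "trials.tsv")

  if ("simulate" %in% stages) {
    trials <- simulate_experiment(config$n_sessions, config$conditions,
                                  config$agent, config$n_trials,
                                  seed = config$seed,
                                  accuracy_convention = config$accuracy_convention)
    write_events(trials, trials_path)
    note(trials_path)
    for (sid in unique(trials$session_id)) {
      for (cond in config$conditions) {
        sess <- trials[trials$session_id == sid & trials$condition == cond, ]
        ts <- simulate_roi_bold(sess, config$effects, roi = "dmFPC",
                                tr = config$tr, seed = config$seed)
        note(write_roi_series(ts, file.path(out_dir,
             sprintf("bold_%s_%s_dmFPC.tsv", sid, cond))))
      }
    }
    log_stage("simulate", sprintf("sessions=%d trials/block=%d",
                                  config$n_sessions, config$n_trials))
  }

  if (any(c("behavior", "glm", "timecourse", "report") %in% stages)) {
    if (!file.exists(trials_path)) {
      stop_param("stage requires missing upstream output: ", trials_path)
    }
    trials <- read_events(trials_path)
  }

  if ("behavior" %in% stages) {
    fits <- list()
    for (cond in intersect(config$conditions, unique(trials$condition))) {
      fits[[paste0("lmm1.", cond)]] <- fit_choice_model(trials, cond)
      fits[[paste0("lmm2.", cond)]] <- fit_accuracy_congruency_model(trials, cond)
    }
    note_path <- file.path(out_dir, "behavior_models.tsv")
    write_behavior_report(fits, note_path)
    note(note_path)
    log_stage("behavior", sprintf("models=%d", length(fits)))
  }

  if ("glm" %in% stages) {
    sids <- unique(trials$session_id)
    fits <- lapply(sids, function(sid) {
      cond <- config$conditions[1]
      sess <- trials[trials$session_id == sid & trials$condition == cond, ]
      ts <- read_roi_series(file.path(out_dir,
              sprintf("bold_%s_%s_dmFPC.tsv", sid, cond)))
      des <- suppressWarnings(build_design(sess, "GLM3",
                                           confounds = ts$confounds,
                                           tr = ts$tr,
                                           n_timepoints = length(ts$values)))
      des <- highpass_design(des)
      fit_glm(highpass_filter(ts$values, ts$tr), des)
    })
    keys <- c(face = 1, congruent = -1)
    grp <- contrast_group(fits, keys)
    path <- file.path(out_dir, "glm_contrast.json")
    jsonlite::write_json(grp[c("estimate", "se", "t", "df", "p")], path,
                         auto_unbox = TRUE, digits = NA)
    note(path)
    log_stage("glm", sprintf("sessions=%d contrast=face-congruent", length(fits)))
  }

  if ("timecourse" %in% stages) {
    cond <- config$conditions[1]
    sessions <- lapply(unique(trials$session_id), function(sid) {
      sess <- trials[trials$session_id == sid & trials$condition == cond, ]
      ts <- read_roi_series(file.path(out_dir,
              sprintf("bold_%s_%s_dmFPC.tsv", sid, cond)))
      up <- preprocess_timecourse(ts)
      ep <- suppressWarnings(extract_epochs(up, sess$onset_decision, window = 7))
      kept <- attr(ep, "kept")
      list(epochs = ep, labels = as.numeric(!sess$congruent[kept]),
           rt = sess$rt[kept])
    })
    pr <- permutation_inference(sessions, n_perm = config$n_perm,
                                window = config$window, seed = config$seed)
    tab <- data.frame(time = pr$time_axis, beta = pr$observed,
                      p_raw = pr$p_raw, p_fdr = pr$p_fdr)
    path <- file.path(out_dir, "timecourse_dmFPC.tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path)
    log_stage("timecourse", sprintf("n_perm=%d window=%gs", config$n_perm,
                                    config$window))
  }

  if ("report" %in% stages) {
    beh_path <- file.path(out_dir, "behavior_models.tsv")
    if (!file.exists(beh_path)) {
      stop_param("stage requires missing upstream output: ", beh_path)
    }
    beh <- utils::read.table(beh_path, sep = "\t", header = TRUE)
    keep <- beh$term %in% c("facedirection", "objectdirection", "incongruency")
    wide <- beh[keep, c("model", "condition", "term", "estimate",
                        "ci_low", "ci_high")]
    path <- file.path(out_dir, "coefficients_by_condition.tsv")
    utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path)
    log_stage("report", sprintf("rows=%d", nrow(wide)))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
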