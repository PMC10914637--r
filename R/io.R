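#' Write a session's trials as a BIDS-events-style TSV
#'
#' One file per session: tab-separated, UTF-8, mandatory header, with the
#' standard `onset`, `duration`, `trial_type` columns first (onset of the
#' decision event; duration = reaction time where available) followed by the
#' full trial record. Unknown extra columns are preserved.
#'
#' @param trials Trial data.frame (one or more sessions).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(trials, path) {
  df <- trials
  df$onset <- df$onset_decision
  df$duration <- ifelse(is.na(df$rt), 1, df$rt)
  df$trial_type <- df$condition
  front <- c("onset", "duration", "trial_type")
  df <- df[, c(front, setdiff(names(df), front))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

events_enums <- list(
  face_direction = c("left", "right"),
  better_object_side = c("left", "right"),
  rewarded_side = c("left", "right"),
  choice = c("left", "right", "none"),
  condition = c("Face", "Object", "Mixed"),
  tus_site = c("sham", "dmFPC", "mSTS", "EVC")
)

#' Read a session events TSV back into trial records
#'
#' Validates the header, non-negative onsets, and the enum-valued columns;
#' parse failures report the offending row. Columns the writer did not emit
#' are preserved as-is.
#'
#' @param path Events TSV path.
#' @return Trial data.frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_param("no such events file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("onset", "duration", "trial_type")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_param("malformed events header; missing column(s): ",
               paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(df$onset) | df$onset < 0)
  if (length(bad)) {
    stop_param(sprintf("negative or missing onset at row %d", bad[1]))
  }
  for (col in intersect(names(events_enums), names(df))) {
    ok <- df[[col]] %in% events_enums[[col]] | is.na(df[[col]])
    if (!all(ok)) {
      stop_param(sprintf("unknown %s value '%s' at row %d",
                         col, df[[col]][which(!ok)[1]], which(!ok)[1]))
    }
  }
  df
}

#' Write / read an ROI series as a delimited matrix plus JSON sidecar
#'
#' The matrix is time x `[signal, confound_1..k]`, tab-separated with a
#' header; the sidecar (same path with `.json`) records `tr`, `roi_label`,
#' `session_id` and the ground-truth effect sizes when present.
#'
#' @param series A `roi_timeseries`.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly (`write_roi_series`); a `roi_timeseries`
#'   (`read_roi_series`).
#' @export
write_roi_series <- function(series, path) {
  m <- cbind(signal = series$values, series$confounds)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(tr = series$tr, roi_label = series$roi_label,
               session_id = series$session_id)
  if (!is.null(series$ground_truth)) {
    meta$ground_truth <- unclass(series$ground_truth)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_series
#' @param path Input `.tsv` path (with an accompanying `.tsv.json` sidecar).
#' @export
read_roi_series <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    gt <- do.call(ground_truth_effects, meta$ground_truth[
      intersect(names(meta$ground_truth), names(formals(ground_truth_effects)))])
  }
  structure(list(values = as.numeric(m[, 1]),
                 tr = meta$tr,
                 roi_label = meta$roi_label,
                 confounds = m[, -1, drop = FALSE],
                 session_id = meta$session_id,
                 ground_truth = gt),
            class = "roi_timeseries")
}

#' Write a behavioral model results table
#'
#' One row per fixed effect: model, condition, term, estimate, ci_low,
#' ci_high, F, df1, df2, p, fell_back_to_fixed.
#'
#' @param fits Named list of `cue_mixed_fit` (names like
#'   `"lmm1.Face"`).
#' @param path Output TSV path.
#' @return The assembled data.frame, invisibly.
#' @export
write_behavior_report <- function(fits, path) {
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    fe <- fit$fixed_effects
    data.frame(model = parts[1],
               condition = if (length(parts) > 1) parts[2] else NA_character_,
               term = fe$term, estimate = fe$estimate,
               ci_low = fe$ci_low, ci_high = fe$ci_high,
               F = fe$f, df1 = fe$df1, df2 = fe$df2, p = fe$p,
               fell_back_to_fixed = fit$fell_back_to_fixed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
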