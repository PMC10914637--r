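#!/usr/bin/env Rscript
# Trial-epoch time-course inference on the simulated ROI series from script
# 04: residualize motion stand-ins, upsample to 10 samples/TR, epoch 0-7 s
# around each decision, regress each timepoint on incongruency and RT, and
# test the cross-session mean beta with a within-session label-shuffle
# permutation test (FDR across 0-3 s timepoints, Holm across ROIs).

suppressMessages(library(socialcue))
seed <- 1
n_sessions <- 16
n_perm <- 1000
dir.create("results", showWarnings = FALSE)

collect_sessions <- function(cond, roi) {
  lapply(seq_len(n_sessions), function(i) {
    sid <- sprintf("s%02d", i)
    trials <- read_events(sprintf("scratch/bold/trials_%s_%s.tsv", sid, cond))
    ts <- read_roi_series(sprintf("scratch/bold/bold_%s_%s_%s.tsv",
                                  sid, cond, roi))
    up <- preprocess_timecourse(ts)
    ep <- suppressWarnings(extract_epochs(up, trials$onset_decision, window = 7))
    kept <- attr(ep, "kept")
    list(epochs = ep, labels = as.numeric(!trials$congruent[kept]),
         rt = trials$rt[kept])
  })
}

min_p <- list()
for (cond in c("Face", "Object")) {
  for (roi in c("dmFPC", "EVC", "mSTS")) {
    pr <- permutation_inference(collect_sessions(cond, roi), n_perm = n_perm,
                                window = 3, seed = seed)
    tab <- data.frame(time = pr$time_axis, beta = pr$observed,
                      p_raw = pr$p_raw, p_fdr = pr$p_fdr)
    write.table(tab, sprintf("results/timecourse_%s_%s.tsv", cond, roi),
                sep = "\t", quote = FALSE, row.names = FALSE)
    min_p[[paste(cond, roi, sep = ".")]] <- min(pr$p_fdr, na.rm = TRUE)
    peak <- mean(pr$observed[pr$time_axis >= 2 & pr$time_axis <= 4])
    cat(sprintf("%-6s %-5s incongruency beta around peak: %+.3f (min pFDR = %.3g)\n",
                cond, roi, peak, min(pr$p_fdr, na.rm = TRUE)))
  }
}

for (cond in c("Face", "Object")) {
  sel <- grep(paste0("^", cond, "\\."), names(min_p), value = TRUE)
  p_roi <- setNames(unlist(min_p[sel]), sub(".*\\.", "", sel))
  adj <- holm_across_rois(p_roi)
  cat(sprintf("%s condition, Holm across ROIs of min pFDR: %s\n", cond,
              paste(sprintf("%s=%.3g", names(adj), adj), collapse = ", ")))
}
cat("Wrote results/timecourse_<condition>_<roi>.tsv\n")
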