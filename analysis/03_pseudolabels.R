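#!/usr/bin/env Rscript
# Stage 3: expand the sparse assessments to daily pseudo-labels by the three
# interpolation methods and measure their fidelity against the generator's
# ground-truth latent trajectories (an audit no real study could run).

suppressMessages({library(alstrack); library(data.table)})

seed <- 20260101L
assessments <- fread("scratch/cohort/assessments.csv")
assessments[, date := as.Date(date)]
latent <- fread("scratch/cohort/latent.csv")
start <- as.Date("2023-01-01")

fidelity <- list()
for (pid in unique(assessments$participant_id)) {
  D <- max(latent[participant_id == pid]$day)
  feats <- fread(sprintf("scratch/features/features_%s.csv", pid))
  feats[, date := as.Date(date)]
  feats[, day := as.integer(date - start)]
  cols <- setdiff(names(feats), c("date", "day"))
  tabs <- lapply(split(cols, sub("__.*$", "", cols)), function(cc) {
    feats[, c("date", "day", cc), with = FALSE]
  })
  for (sc in c("speech", "swallowing", "walking", "composite")) {
    truth <- latent[participant_id == pid & scale_id == sc][order(day)]$value
    series <- list(
      linear = interpolate_linear(assessments, 0:D, pid, sc, start),
      cubic = interpolate_cubic(assessments, 0:D, pid, sc, start),
      attention = interpolate_attention(
        tabs, assessments, pid, sc, 0:D,
        attention_config(epochs = 60, seed = derive_seed(seed, "att", pid, sc)),
        start))
    for (meth in names(series)) {
      fidelity[[length(fidelity) + 1L]] <- data.table(
        participant_id = pid, scale_id = sc, method = meth,
        rmse_vs_latent = rmse(truth, series[[meth]]$value),
        r_vs_latent = pearson_r(truth, series[[meth]]$value)$r)
    }
  }
}
fid <- rbindlist(fidelity)
fwrite(fid, "results/pseudolabel_fidelity.csv")
cat("Pseudo-label fidelity against the latent ground truth:\n")
print(fid[, .(mean_rmse = round(mean(rmse_vs_latent), 3),
              mean_r = round(mean(r_vs_latent), 3)),
          by = .(scale_id, method)])
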