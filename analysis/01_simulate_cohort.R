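#!/usr/bin/env Rscript
# Stage 1: generate the synthetic monitoring cohort under the study
# conditions (3 participants, enrollment 599/236/219 days, monthly
# assessments with quarterly clinic visits, coupled sensor channels).
# Raw streams go to scratch/ (large); summary tables to results/.

suppressMessages({library(alstrack); library(data.table)})

seed <- 20260101L
cfg <- cohort_config(seed = seed, bed_samples_per_day = 144)
cohort <- generate_cohort(cfg, out_dir = "scratch/cohort")

dir.create("results", showWarnings = FALSE)

assess_summary <- cohort$assessments[, .(
  assessments = .N,
  first_composite = composite[1],
  last_composite = composite[.N]
), by = participant_id]
enrollment <- data.table(participant_id = cfg$participant_ids,
                         enrollment_days = cfg$enrollment_days)
summary_tab <- merge(enrollment, assess_summary, by = "participant_id")
score_var <- cohort$assessments[, lapply(.SD, var), by = participant_id,
                                .SDcols = ALSFRS_SUBSCALES]

fwrite(summary_tab, "results/cohort_summary.csv")
fwrite(score_var, "results/cohort_score_variance.csv")

cat("Cohort generated (seed", seed, "):\n")
print(summary_tab)
cat("\nSubscale score variances (cf. the 0.00-2.41 range observed in",
    "comparable case series):\n")
print(score_var[, lapply(.SD, round, 2), by = participant_id])
cat("\nSensor stream rows:", nrow(cohort$streams),
    "| raw CSVs under scratch/cohort/\n")
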