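#!/usr/bin/env Rscript
# Step 1: generate the study-sized synthetic cohort.
#
# 43 subjects, two visits (screening, baseline), mesopic (4 lux) and
# photopic (300 lux) conditions, five tolerability-checked repeats per
# session, right eye. Trace-level artifacts (noise, blinks, pupillary
# escape, latent constrictions) are on at their defaults. Takes a few
# seconds; writes ~25 MB of trace CSV under results/data/.

suppressMessages(library(pupilagree))

seed <- 20230131L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cp <- cohort_params(n_subjects = 43, seed = seed)
sim <- simulate_cohort(cp)

write_traces(sim$traces, file.path(out_dir, "traces.csv"))
readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))
write_cohort_config(cp, file.path(out_dir, "cohort_config.yaml"))

n_sessions <- nrow(dplyr::distinct(sim$traces, subject_id, visit,
                                   condition))
cat(sprintf("simulated %d subjects / %d sessions / %d samples\n",
            cp$n_subjects, n_sessions, nrow(sim$traces)))
cat(sprintf("blinks left %d samples invalid (%.1f%%)\n",
            sum(!sim$traces$device_valid),
            100 * mean(!sim$traces$device_valid)))
cat("ground truth is written separately and never read by the pipeline\n")
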