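#!/usr/bin/env Rscript
# Step 2: read every session with both methods.
#
# Automated reading: Hampel/MAD pass, validity + plausibility + step
# filters, median and 10th percentile over the 2-4 s post-onset window,
# quality-weighted robust mean across repeats (q > 0.5 only).
# Human-assisted emulation: whole-stimulus minimum per repeat, averaged.

suppressMessages(library(pupilagree))

traces <- read_traces("results/data/traces.csv", strict = TRUE)
cfg <- filter_config()
readings <- read_sessions(traces, cfg, eye = "right")

dir.create("results", showWarnings = FALSE)
write_readings(readings, "results/readings.csv")

below <- sum(readings$n_repeats_used == 0)
cat(sprintf("read %d sessions -> %d reading records\n",
            nrow(readings) / 2, nrow(readings)))
cat(sprintf("%d session reading(s) fell below the quality threshold\n",
            below))
print(descriptive_table(readings), n = 8)
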