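#!/usr/bin/env Rscript
# Step 3: Bland-Altman agreement, over time and between reading
# methods, per light condition.
#
# Four comparisons per condition: screening vs baseline on
# human-assisted and on automated readings, and automated vs
# human-assisted at each visit. Each comparison reports bias, limits of
# agreement, the agreement/repeatability coefficient and exact t-based
# 95% CIs, with single-pass 3 SD outlier exclusion; a significant
# correlation between differences and averages triggers the ratio-scale
# analysis. Re-reads the sessions, so allow ~half a minute.

suppressMessages(library(pupilagree))

traces <- read_traces("results/data/traces.csv", strict = TRUE)
pipe <- run_pipeline(traces, eye = "right", alpha = 0.05)

write_pipeline_report(pipe, "results")
print(pipe)

for (key in names(pipe$agreement)) {
  res <- pipe$agreement[[key]]
  if (res$triggered) {
    rr <- res$ratio[nrow(res$ratio), ]
    cat(sprintf(
      "%s: proportional bias (p = %.3g) -> ratio scale: %.3f (%.3f to %.3f)\n",
      key, res$trigger_p, rr$bias, rr$ci_bias_lower, rr$ci_bias_upper))
  }
}
cat("wrote agreement tables, Bland-Altman and Q-Q plot data under results/\n")
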