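#!/usr/bin/env Rscript
# Step 4: render the rounded summary tables from the unrounded report.
#
# Table analogues: descriptive mean (SD) pupil sizes per condition x
# visit x method; difference-scale agreement rows (2 dp, mm); ratio
# rows where triggered (3 dp). Rounding happens only here -- every
# upstream artifact keeps full precision.

suppressMessages({
  library(pupilagree)
  library(dplyr)
})

report <- jsonlite::read_json("results/report.json",
                              simplifyVector = TRUE)

desc <- as_tibble(report$descriptives) |>
  mutate(mean_sd = sprintf("%.2f (%.2f)", mean_mm, sd_mm)) |>
  select(condition, visit, method, n, mean_sd)
readr::write_csv(desc, "results/table_descriptives.csv")
cat("Descriptive pupil sizes, mean (SD) mm:\n")
print(as.data.frame(desc))

fmt_row <- function(r, dp) {
  f <- function(x) formatC(x, digits = dp, format = "f")
  sprintf("%-28s %-18s n=%2d  bias %s (%s to %s)  LOA %s (%s to %s) / %s (%s to %s)  coef %s  r=%.2f p=%.3g",
          r$comparison, paste0(r$scale, "/", r$pass), r$n, f(r$bias),
          f(r$ci_bias_lower), f(r$ci_bias_upper), f(r$loa_lower),
          f(r$ci_loa_lower_lower), f(r$ci_loa_lower_upper),
          f(r$loa_upper), f(r$ci_loa_upper_lower),
          f(r$ci_loa_upper_upper), f(r$coefficient), r$pearson_r,
          r$pearson_p)
}

agree <- as_tibble(report$agreement)
readr::write_csv(agree |> filter(scale == "difference"),
                 "results/table_agreement_difference.csv")
cat("\nAgreement (difference scale, mm):\n")
for (i in which(agree$scale == "difference")) {
  cat(fmt_row(agree[i, ], 2), "\n")
}
if (any(agree$scale == "ratio")) {
  readr::write_csv(agree |> filter(scale == "ratio"),
                   "results/table_agreement_ratio.csv")
  cat("\nAgreement (ratio scale):\n")
  for (i in which(agree$scale == "ratio")) {
    cat(fmt_row(agree[i, ], 3), "\n")
  }
}
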