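# Orchestration: traces -> per-session readings -> descriptive table ->
# agreement analyses (over time and between reading methods, per light
# condition) -> plot data and a machine-readable report.

.supported_comparisons <- c("visits_human", "visits_automated",
                            "methods_screening", "methods_baseline")

#' Run the full reading and agreement pipeline
#'
#' Reads every session of the supplied traces with both methods, builds
#' the descriptive mean (SD) table per condition x visit x method, and
#' runs the four agreement comparisons per light condition: screening
#' vs baseline on human-assisted and on automated readings, and
#' automated vs human-assisted at each visit. Comparisons with fewer
#' than 3 complete pairs are skipped with a recorded reason. The ratio
#' analysis is triggered per comparison by a significant
#' proportional-bias correlation (see [analyze_pair()]).
#'
#' @param traces Long trace tibble (e.g. from [read_traces()] or
#'   [simulate_cohort()]).
#' @param cfg A [filter_config()].
#' @param eye Eye analyzed (default right, the analysis convention).
#' @param conditions Light conditions to analyze.
#' @param comparisons Subset of
#'   `c("visits_human", "visits_automated", "methods_screening",
#'   "methods_baseline")`.
#' @param alpha Significance level for the ratio trigger.
#' @param sd_multiplier Outlier cut in SD units.
#'
#' @return List of class `"pupil_pipeline"`: `readings`,
#'   `descriptives`, `agreement` (named list of [analyze_pair()]
#'   results, keys `<condition>.<comparison>`), `plot_data`
#'   (Bland-Altman points/lines and Q-Q pairs per comparison),
#'   `skipped`, and `meta` (package version, config and its hash).
#' @export
run_pipeline <- function(traces, cfg = filter_config(), eye = "right",
                         conditions = c("mesopic", "photopic"),
                         comparisons = .supported_comparisons,
                         alpha = 0.05, sd_multiplier = 3) {
  comparisons <- match.arg(comparisons, .supported_comparisons,
                           several.ok = TRUE)
  readings <- read_sessions(traces, cfg, eye = eye)
  descriptives <- descriptive_table(readings)
  agreement <- list()
  plot_data <- list()
  skipped <- list()
  for (cond in conditions) {
    for (cmp in comparisons) {
      pm <- switch(cmp,
        visits_human = paired_measurements(readings, "visits",
                                           condition = cond, eye = eye,
                                           method = "human"),
        visits_automated = paired_measurements(readings, "visits",
                                               condition = cond,
                                               eye = eye,
                                               method = "automated"),
        methods_screening = paired_measurements(readings, "methods",
                                                condition = cond,
                                                eye = eye,
                                                visit = "screening"),
        methods_baseline = paired_measurements(readings, "methods",
                                               condition = cond,
                                               eye = eye,
                                               visit = "baseline")
      )
      key <- paste(cond, cmp, sep = ".")
      if (nrow(pm) < 3) {
        skipped[[key]] <- sprintf("only %d complete pairs", nrow(pm))
        next
      }
      res <- analyze_pair(pm, alpha = alpha,
                          sd_multiplier = sd_multiplier)
      agreement[[key]] <- res
      plot_data[[key]] <- comparison_plot_data(pm, res)
    }
  }
  structure(
    list(readings = readings, descriptives = descriptives,
         agreement = agreement, plot_data = plot_data,
         skipped = skipped,
         meta = list(
           package_version = as.character(packageVersion("pupilagree")),
           eye = eye, alpha = alpha, sd_multiplier = sd_multiplier,
           config = unclass(cfg), config_hash = rlang::hash(unclass(cfg))
         )),
    class = "pupil_pipeline"
  )
}

#' Descriptive mean (SD) table of readings
#'
#' @param readings Reading-record tibble.
#' @return Tibble with `condition`, `visit`, `method`, `n` (non-missing
#'   readings), `mean_mm`, `sd_mm`.
#' @export
descriptive_table <- function(readings) {
  readings %>%
    group_by(.data$condition, .data$visit, .data$method) %>%
    summarise(n = sum(!is.na(.data$pupil_mm)),
              mean_mm = mean(.data$pupil_mm, na.rm = TRUE),
              sd_mm = sd(.data$pupil_mm, na.rm = TRUE),
              .groups = "drop")
}

# Bland-Altman point/line data plus Q-Q pairs for one comparison, on
# the comparison's headline scale.
comparison_plot_data <- function(pm, res) {
  scale <- res$headline
  tab <- if (scale == "ratio") res$ratio else res$difference
  row <- tab[nrow(tab), ]
  v <- if (scale == "ratio") pm$a / pm$b else pm$a - pm$b
  points <- tibble(
    subject_id = pm$subject_id,
    average = (pm$a + pm$b) / 2,
    value = v,
    outlier = pm$subject_id %in% row$outliers[[1]]
  )
  lines <- tibble(
    scale = scale, bias = row$bias,
    loa_lower = row$loa_lower, loa_upper = row$loa_upper,
    ci_bias_lower = row$ci_bias_lower, ci_bias_upper = row$ci_bias_upper,
    ci_loa_lower_lower = row$ci_loa_lower_lower,
    ci_loa_lower_upper = row$ci_loa_lower_upper,
    ci_loa_upper_lower = row$ci_loa_upper_lower,
    ci_loa_upper_upper = row$ci_loa_upper_upper
  )
  use <- if (row$pass == "outliers_excluded") !points$outlier else {
    rep(TRUE, nrow(points))
  }
  qq <- qq_data(v[use])
  list(points = points, lines = lines, qq = qq)
}

# Flatten one analyze_pair() result into report rows.
.agreement_rows <- function(key, res) {
  rows <- res$difference
  if (!is.null(res$ratio)) {
    rows <- bind_rows(rows, res$ratio)
  }
  rows$comparison <- key
  rows$headline <- res$headline
  rows$outliers <- vapply(rows$outliers, paste, character(1),
                          collapse = ";")
  select(rows, "comparison", "scale", "pass", dplyr::everything())
}

#' Export a pipeline report bundle
#'
#' Writes the readings and descriptive CSVs, one agreement CSV per
#' scale, Bland-Altman and Q-Q plot-data CSVs, and `report.json`
#' carrying all numbers unrounded plus a rounded table block (2
#' decimals on the mm scale, 3 on the ratio scale), the package
#' version, the configuration and its hash.
#'
#' @param pipeline A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(pipeline$readings, file.path(dir, "readings.csv"),
                   na = "")
  readr::write_csv(pipeline$descriptives,
                   file.path(dir, "descriptives.csv"))
  rows <- map_dfr(names(pipeline$agreement), function(k) {
    .agreement_rows(k, pipeline$agreement[[k]])
  })
  for (sc in unique(rows$scale)) {
    readr::write_csv(filter(rows, .data$scale == sc),
                     file.path(dir, paste0("agreement_", sc, ".csv")))
  }
  for (k in names(pipeline$plot_data)) {
    pd <- pipeline$plot_data[[k]]
    readr::write_csv(pd$points,
                     file.path(dir, paste0("ba_points_", k, ".csv")))
    readr::write_csv(pd$lines,
                     file.path(dir, paste0("ba_lines_", k, ".csv")))
    readr::write_csv(pd$qq, file.path(dir, paste0("qq_", k, ".csv")))
  }
  rounded <- rows
  num <- vapply(rounded, is.numeric, logical(1))
  for (nm in names(rounded)[num]) {
    rounded[[nm]] <- ifelse(rounded$scale == "ratio",
                            round(rounded[[nm]], 3),
                            round(rounded[[nm]], 2))
  }
  rounded$n <- rows$n
  report <- list(
    meta = pipeline$meta,
    descriptives = pipeline$descriptives,
    agreement = rows,
    agreement_rounded = rounded,
    skipped = pipeline$skipped
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.pupil_pipeline <- function(x, ...) {
  cat("pupil reading pipeline:",
      nrow(distinct(x$readings, .data$subject_id)), "subjects,",
      nrow(x$readings), "readings\n")
  for (k in names(x$agreement)) {
    res <- x$agreement[[k]]
    row <- res$difference[nrow(res$difference), ]
    cat(sprintf("  %-28s n=%2d bias=%6.3f LOA=[%6.3f, %6.3f]%s\n",
                k, row$n, row$bias, row$loa_lower, row$loa_upper,
                if (res$triggered) " (ratio triggered)" else ""))
  }
  for (k in names(x$skipped)) {
    cat("  skipped", k, "-", x$skipped[[k]], "\n")
  }
  invisible(x)
}
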