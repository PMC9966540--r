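# Bland-Altman agreement between two measurement sets (visits or reading
# methods): bias, limits of agreement, exact t-based confidence
# intervals, single-pass outlier policy, proportional-bias test and the
# ratio-scale fallback.

#' Closed-form Bland-Altman confidence intervals
#'
#' From a bias, a spread and a sample size, computes the limits of
#' agreement (LOA) `bias +/- 1.96 * sd`, the agreement/repeatability
#' coefficient `1.96 * sd`, the standard errors `SE(bias) = sqrt(sd^2/n)`
#' and `SE(LOA) = sqrt(3 sd^2/n)`, and two-sided confidence intervals
#' `estimate +/- t * SE` using the t distribution with n - 1 degrees of
#' freedom. Either `sd` or the printed `coefficient` (from which
#' `sd = coefficient / 1.96`) may be supplied, so published summary rows
#' can be re-expanded into their interval estimates.
#'
#' @param bias Mean difference (or mean ratio).
#' @param n Sample size.
#' @param sd Standard deviation of the per-subject differences/ratios.
#' @param coefficient Alternatively, the agreement coefficient
#'   `1.96 * sd`.
#' @param conf_level Confidence level (default 0.95).
#' @param loa_z Multiplier in the LOA definition (1.96 by convention;
#'   the t quantile is used only for the confidence intervals).
#'
#' @return One-row tibble with the point estimates, standard errors,
#'   the t quantile and all interval bounds.
#' @export
loa_confint <- function(bias, n, sd = NULL, coefficient = NULL,
                        conf_level = 0.95, loa_z = 1.96) {
  if (is.null(sd) && is.null(coefficient)) {
    abort("supply either sd or coefficient")
  }
  if (is.null(sd)) {
    sd <- coefficient / loa_z
  }
  if (n < 2) {
    abort("loa_confint requires n >= 2")
  }
  coefficient <- loa_z * sd
  se_bias <- sqrt(sd^2 / n)
  se_loa <- sqrt(3 * sd^2 / n)
  t_crit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  loa_lower <- bias - coefficient
  loa_upper <- bias + coefficient
  tibble(
    n = as.integer(n), bias = bias, sd = sd, coefficient = coefficient,
    loa_lower = loa_lower, loa_upper = loa_upper,
    se_bias = se_bias, se_loa = se_loa, t_crit = t_crit,
    ci_bias_lower = bias - t_crit * se_bias,
    ci_bias_upper = bias + t_crit * se_bias,
    ci_loa_lower_lower = loa_lower - t_crit * se_loa,
    ci_loa_lower_upper = loa_lower + t_crit * se_loa,
    ci_loa_upper_lower = loa_upper - t_crit * se_loa,
    ci_loa_upper_upper = loa_upper + t_crit * se_loa
  )
}

#' Build paired measurements from reading records
#'
#' Joins two sides of a comparison (two visits read with one method, or
#' two reading methods at one visit) into per-subject pairs for one eye
#' and light condition. Subjects with a missing member on either side
#' are dropped pairwise and counted, reproducing the reduced-N pattern
#' caused by below-quality sessions.
#'
#' @param readings Reading-record tibble (see [read_sessions()]).
#' @param compare `"visits"` or `"methods"`.
#' @param condition Light condition to compare.
#' @param eye Eye to compare.
#' @param method For `compare = "visits"`: the reading method used on
#'   both sides.
#' @param visit For `compare = "methods"`: the visit compared.
#' @param orientation Length-2 character naming the `a` and `b` sides.
#'   Defaults: visits compare a = screening vs b = baseline; methods
#'   compare a = automated vs b = human, so that a larger automated
#'   reading yields positive differences and ratios above 1.
#'
#' @return Tibble with columns `subject_id`, `a`, `b`; attributes
#'   `labels` (the two side names) and `n_dropped` (incomplete pairs).
#' @export
paired_measurements <- function(readings, compare = c("visits", "methods"),
                                condition = "mesopic", eye = "right",
                                method = "human", visit = "screening",
                                orientation = NULL) {
  compare <- match.arg(compare)
  if (compare == "visits") {
    sides <- orientation %||% c("screening", "baseline")
    sub <- filter(readings, .data$condition == !!condition,
                  .data$eye == !!eye, .data$method == !!method,
                  .data$visit %in% sides)
    side_col <- "visit"
  } else {
    sides <- orientation %||% c("automated", "human")
    sub <- filter(readings, .data$condition == !!condition,
                  .data$eye == !!eye, .data$visit == !!visit,
                  .data$method %in% sides)
    side_col <- "method"
  }
  wide <- sub %>%
    select("subject_id", side = all_of(side_col), "pupil_mm") %>%
    tidyr::pivot_wider(names_from = "side", values_from = "pupil_mm")
  for (s in sides) {
    if (!s %in% names(wide)) wide[[s]] <- NA_real_
  }
  complete <- !is.na(wide[[sides[1]]]) & !is.na(wide[[sides[2]]])
  out <- tibble(subject_id = wide$subject_id[complete],
                a = wide[[sides[1]]][complete],
                b = wide[[sides[2]]][complete])
  attr(out, "labels") <- sides
  attr(out, "n_dropped") <- sum(!complete)
  out
}

.pair_values <- function(pairs, scale) {
  if (scale == "ratio") {
    if (any(pairs$b <= 0 | pairs$a <= 0)) {
      abort("ratio scale requires strictly positive measurements")
    }
    pairs$a / pairs$b
  } else {
    pairs$a - pairs$b
  }
}

#' Bland-Altman agreement analysis
#'
#' Computes per-subject differences `a - b` (or ratios `a / b`), the
#' bias, sample SD (n - 1 denominator), limits of agreement, the
#' agreement coefficient, exact t-based confidence intervals for bias
#' and both LOA, and the Pearson correlation of values against averages
#' (proportional-bias check). Outliers, defined on the all-data fit as
#' values more than `sd_multiplier` SDs from the bias, are removed in a
#' single pass and the analysis recomputed; both rows are reported.
#'
#' @param pairs Paired measurements (tibble with `subject_id`, `a`, `b`;
#'   see [paired_measurements()]). Pairs must be complete.
#' @param scale `"difference"` or `"ratio"`.
#' @param exclude_outliers Whether to run the outlier-exclusion pass.
#' @param sd_multiplier Outlier cut in SD units (default 3).
#' @param conf_level Confidence level for all intervals.
#'
#' @return Tibble with one row per pass (`"all"` and, when outliers were
#'   found, `"outliers_excluded"`): the [loa_confint()] columns plus
#'   `pass`, `scale`, `pearson_r`, `pearson_p`, `n_outliers`,
#'   `outliers` (list column of subject ids) and `degenerate`.
#' @export
bland_altman <- function(pairs, scale = c("difference", "ratio"),
                         exclude_outliers = TRUE, sd_multiplier = 3,
                         conf_level = 0.95) {
  scale <- match.arg(scale)
  if (anyNA(pairs$a) || anyNA(pairs$b)) {
    abort("pairs must be complete; drop incomplete pairs upstream")
  }
  if (anyDuplicated(pairs$subject_id)) {
    abort("subject ids must be unique within a comparison")
  }
  if (nrow(pairs) < 3) {
    abort("bland_altman requires at least 3 pairs")
  }
  one_pass <- function(p, pass) {
    v <- .pair_values(p, scale)
    res <- loa_confint(bias = mean(v), n = length(v), sd = sd(v),
                       conf_level = conf_level)
    pb <- proportional_bias(p, scale)
    res$pass <- pass
    res$scale <- scale
    res$pearson_r <- pb$r
    res$pearson_p <- pb$p
    res$degenerate <- sd(v) == 0
    res
  }
  all_res <- one_pass(pairs, "all")
  v <- .pair_values(pairs, scale)
  out_idx <- abs(v - all_res$bias) > sd_multiplier * all_res$sd
  all_res$n_outliers <- sum(out_idx)
  all_res$outliers <- list(pairs$subject_id[out_idx])
  res <- all_res
  if (exclude_outliers && any(out_idx) && sum(!out_idx) >= 3) {
    excl <- one_pass(pairs[!out_idx, , drop = FALSE], "outliers_excluded")
    excl$n_outliers <- sum(out_idx)
    excl$outliers <- list(pairs$subject_id[out_idx])
    res <- bind_rows(all_res, excl)
  }
  res
}

#' Proportional-bias test
#'
#' Two-sided Pearson correlation between the per-subject values
#' (differences or ratios) and the per-subject averages `(a + b) / 2`.
#' A significant correlation indicates that the disagreement grows with
#' the magnitude of the measurement, in which case the ratio scale gives
#' more valid limits of agreement.
#'
#' @inheritParams bland_altman
#' @return List with `r`, `p` and `degenerate` (`TRUE` when either
#'   vector has zero variance, in which case `r` and `p` are `NA`).
#' @export
proportional_bias <- function(pairs, scale = c("difference", "ratio")) {
  scale <- match.arg(scale)
  if (nrow(pairs) < 3) {
    abort("proportional_bias requires at least 3 pairs")
  }
  v <- .pair_values(pairs, scale)
  avg <- (pairs$a + pairs$b) / 2
  if (sd(v) == 0 || sd(avg) == 0) {
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ct <- cor.test(v, avg, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Full agreement analysis with ratio fallback
#'
#' Runs the difference-scale Bland-Altman analysis and its
#' proportional-bias test; when the correlation between differences and
#' averages is significant at `alpha` (judged on the outlier-excluded
#' pass when one exists), the analysis is repeated on the ratio scale,
#' which is equivalent to a logarithmic transformation.
#'
#' @inheritParams bland_altman
#' @param alpha Significance level for the proportional-bias trigger.
#' @param ratio `"auto"` triggers the ratio analysis on a significant
#'   correlation; `"always"`/`"never"` force the choice.
#'
#' @return List of class `"pupil_agreement"`: `difference` and (when
#'   triggered) `ratio` result tibbles, `triggered`, `trigger_p`,
#'   `headline` (the scale to report) and `labels`.
#' @export
analyze_pair <- function(pairs, alpha = 0.05, ratio = c("auto", "always",
                                                        "never"),
                         exclude_outliers = TRUE, sd_multiplier = 3,
                         conf_level = 0.95) {
  ratio <- match.arg(ratio)
  diff_res <- bland_altman(pairs, "difference",
                           exclude_outliers = exclude_outliers,
                           sd_multiplier = sd_multiplier,
                           conf_level = conf_level)
  judge <- diff_res[nrow(diff_res), ]
  trigger_p <- judge$pearson_p
  triggered <- switch(ratio,
    auto = isTRUE(trigger_p < alpha),
    always = TRUE,
    never = FALSE
  )
  ratio_res <- NULL
  if (triggered) {
    ratio_res <- bland_altman(pairs, "ratio",
                              exclude_outliers = exclude_outliers,
                              sd_multiplier = sd_multiplier,
                              conf_level = conf_level)
  }
  structure(
    list(difference = diff_res, ratio = ratio_res,
         triggered = triggered, trigger_p = trigger_p, alpha = alpha,
         headline = if (triggered) "ratio" else "difference",
         labels = attr(pairs, "labels"),
         n_dropped = attr(pairs, "n_dropped") %||% 0L),
    class = "pupil_agreement"
  )
}

#' @export
print.pupil_agreement <- function(x, ...) {
  lb <- x$labels %||% c("a", "b")
  cat("Bland-Altman agreement:", lb[1], "vs", lb[2], "\n")
  row <- x$difference[nrow(x$difference), ]
  cat(sprintf("  difference scale (%s): bias %.3f mm, LOA [%.3f, %.3f]\n",
              row$pass, row$bias, row$loa_lower, row$loa_upper))
  if (!is.null(x$ratio)) {
    rr <- x$ratio[nrow(x$ratio), ]
    cat(sprintf("  ratio scale (%s): mean ratio %.4f, LOA [%.4f, %.4f]\n",
                rr$pass, rr$bias, rr$loa_lower, rr$loa_upper))
  }
  cat(sprintf("  proportional bias p = %.4g -> %s scale is headline\n",
              x$trigger_p, x$headline))
  invisible(x)
}

#' Q-Q plot data for a set of values
#'
#' Pairs the standardized order statistics with standard-normal
#' quantiles at probability points `(i - 0.5) / n`, as data for a visual
#' normality check of paired differences. No automatic accept/reject is
#' performed.
#'
#' @param values Numeric vector, `n >= 3`.
#' @return Tibble with `theoretical`, `sample` (standardized) and
#'   `value` (raw order statistics); attribute `degenerate` is `TRUE`
#'   for constant input (standardization undefined).
#' @export
qq_data <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) {
    abort("qq_data requires at least 3 values")
  }
  v <- sort(values)
  s <- sd(v)
  degenerate <- s == 0
  out <- tibble(
    theoretical = qnorm((seq_len(n) - 0.5) / n),
    sample = if (degenerate) rep(NA_real_, n) else (v - mean(v)) / s,
    value = v
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Log-ratio identity self-test
#'
#' Verifies, per subject, that `log(a / b)` equals `log(a) - log(b)` to
#' numerical tolerance -- the identity that makes the ratio analysis
#' equivalent to a logarithmic transformation.
#'
#' @param pairs Paired measurements with strictly positive `a`, `b`.
#' @param tol Numerical tolerance.
#' @return `TRUE`/`FALSE`, with the maximum absolute deviation in
#'   attribute `max_abs_dev`.
#' @export
log_ratio_equivalence_check <- function(pairs, tol = 1e-12) {
  if (any(pairs$a <= 0 | pairs$b <= 0)) {
    abort("log_ratio_equivalence_check requires positive values")
  }
  dev <- abs(log(pairs$a / pairs$b) - (log(pairs$a) - log(pairs$b)))
  structure(all(dev <= tol), max_abs_dev = max(dev))
}
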