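# Automated reading of minimal pupil size from a raw trace:
# Hampel/MAD outlier removal -> device-validity/range/step filtering ->
# median and 10th percentile over a fixed post-onset window -> quality-
# weighted robust mean across the session's repeats.

#' Filtering and reading configuration
#'
#' Parameters of the automated reading algorithm. Defaults follow the
#' published configuration: a 1.4 s Hampel window with removal when the
#' deviation from the local median exceeds 1.5 mm or 3 times the
#' MAD-based scale estimate; plausibility band 2--9 mm; maximum
#' 0.5 mm step between consecutive retained points (about 15 mm/s at
#' 30 Hz); analysis window 2--4 s after stimulus onset; repeats
#' contribute only when the quality score q exceeds 0.5 (strict); weights
#' w = q * exp(-2 d).
#'
#' @param hampel_window Width of the rolling Hampel window, seconds.
#' @param hampel_t Multiplier on the MAD-based scale estimate.
#' @param hampel_abs Absolute deviation cap, mm.
#' @param min_diameter,max_diameter Plausibility band, mm. Samples
#'   strictly below/above are discarded.
#' @param max_step Maximum allowed diameter change between consecutive
#'   points, mm.
#' @param window_start_offset,window_end_offset Analysis window relative
#'   to stimulus onset, seconds (half-open interval).
#' @param quality_threshold Minimum quality score; repeats qualify only
#'   with `q > quality_threshold` (strict inequality).
#' @param weight_decay Coefficient in the weight `w = q * exp(-weight_decay * d)`.
#' @param hampel_centered Centered (`TRUE`, default) or trailing rolling
#'   window.
#' @param step_anchor `"retained"` (default) compares each candidate
#'   against the most recent retained sample, so an isolated spike does
#'   not cascade into removing the recovered signal; `"raw"` compares
#'   against the previous present raw sample.
#'
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(hampel_window = 1.4, hampel_t = 3,
                          hampel_abs = 1.5, min_diameter = 2,
                          max_diameter = 9, max_step = 0.5,
                          window_start_offset = 2, window_end_offset = 4,
                          quality_threshold = 0.5, weight_decay = 2,
                          hampel_centered = TRUE,
                          step_anchor = c("retained", "raw")) {
  step_anchor <- match.arg(step_anchor)
  cfg <- list(
    hampel_window = hampel_window, hampel_t = hampel_t,
    hampel_abs = hampel_abs, min_diameter = min_diameter,
    max_diameter = max_diameter, max_step = max_step,
    window_start_offset = window_start_offset,
    window_end_offset = window_end_offset,
    quality_threshold = quality_threshold, weight_decay = weight_decay,
    hampel_centered = hampel_centered, step_anchor = step_anchor
  )
  num <- cfg[!names(cfg) %in% c("hampel_centered", "step_anchor")]
  if (any(!vapply(num, function(v) is.numeric(v) && v >= 0, logical(1)))) {
    abort("filter_config parameters must be non-negative numbers")
  }
  if (window_start_offset >= window_end_offset) {
    abort("window_start_offset must be smaller than window_end_offset")
  }
  if (quality_threshold < 0 || quality_threshold > 1) {
    abort("quality_threshold must lie in [0, 1]")
  }
  structure(cfg, class = "filter_config")
}

#' Hampel/MAD outlier pass over one trace
#'
#' For every sample with a present diameter, the median m and the
#' MAD-based scale S = 1.4826 * median(|x_j - m|) are computed over the
#' samples within the rolling window (centered by default, truncated at
#' the trace edges; missing-diameter samples are skipped). The sample is
#' removed when its deviation |x - m| exceeds `hampel_abs` or
#' `hampel_t * S`. When S = 0 (locally constant signal) only the
#' absolute rule applies. Outliers are removed, never replaced.
#'
#' @param trace A single trace (tibble with columns `t_s`,
#'   `diameter_mm`).
#' @param cfg A [filter_config()].
#'
#' @return Logical retention mask, one element per sample; samples with
#'   a missing diameter are marked not retained.
#' @export
hampel_filter <- function(trace, cfg = filter_config()) {
  if (nrow(trace) == 0) {
    abort("hampel_filter: empty trace")
  }
  x_all <- trace$diameter_mm
  t_all <- trace$t_s
  present <- which(!is.na(x_all))
  if (length(present) == 0) {
    abort("hampel_filter: trace has no present diameters")
  }
  x <- x_all[present]
  tt <- t_all[present]
  # inclusive window endpoints, with a small tolerance so samples
  # exactly one half-window away are not dropped by rounding of t
  eps <- 1e-9
  if (cfg$hampel_centered) {
    half <- cfg$hampel_window / 2 + eps
    lo <- findInterval(tt - half, tt, left.open = TRUE) + 1L
    hi <- findInterval(tt + half, tt)
  } else {
    lo <- findInterval(tt - cfg$hampel_window - eps, tt,
                       left.open = TRUE) + 1L
    hi <- seq_along(tt)
  }
  keep <- logical(length(x))
  for (i in seq_along(x)) {
    w <- x[lo[i]:hi[i]]
    m <- median(w)
    dev <- abs(x[i] - m)
    s <- 1.4826 * median(abs(w - m))
    keep[i] <- dev <= cfg$hampel_abs && (s <= 0 || dev <= cfg$hampel_t * s)
  }
  mask <- logical(length(x_all))
  mask[present] <- keep
  mask
}

#' Device-validity, plausibility-band and step filtering
#'
#' Starting from a Hampel retention mask, additionally discards samples
#' flagged invalid by the acquisition software, missing diameters,
#' diameters outside the plausibility band, and samples differing from
#' the most recent retained sample by more than `max_step` (a chain scan
#' in time order; see `step_anchor` in [filter_config()]).
#'
#' @inheritParams hampel_filter
#' @param mask Logical retention mask from [hampel_filter()].
#' @return Updated logical retention mask (may retain zero samples).
#' @export
validity_filter <- function(trace, mask, cfg = filter_config()) {
  d <- trace$diameter_mm
  ok <- mask & !is.na(d) & trace$device_valid &
    d >= cfg$min_diameter & d <= cfg$max_diameter
  ok[is.na(ok)] <- FALSE
  if (cfg$step_anchor == "retained") {
    last <- NA_real_
    for (i in which(ok)) {
      if (!is.na(last) && abs(d[i] - last) > cfg$max_step) {
        ok[i] <- FALSE
      } else {
        last <- d[i]
      }
    }
  } else {
    pres <- which(!is.na(d))
    prev <- c(NA_real_, d[pres[-length(pres)]])
    drop <- !is.na(prev) & abs(d[pres] - prev) > cfg$max_step
    ok[pres[drop]] <- FALSE
  }
  ok
}

#' Per-repeat window statistics
#'
#' Over the analysis window (`stimulus_onset + window_start_offset <= t
#' < stimulus_onset + window_end_offset`), computes the median and 10th
#' percentile of retained diameters (linear-interpolation percentile
#' definition), the quality score q (retained / all samples falling in
#' the window by timestamp), the spread d = |median - p10| and the
#' weight w = q * exp(-weight_decay * d). With no retained samples the
#' estimate carries q = 0, w = 0 and missing percentiles.
#'
#' @inheritParams validity_filter
#' @return One-row tibble with columns `p_median`, `p10`, `q`, `d`, `w`,
#'   `n_total`, `n_retained`.
#' @export
window_estimate <- function(trace, mask, cfg = filter_config()) {
  onset <- trace$stimulus_onset_s[1]
  in_win <- trace$t_s >= onset + cfg$window_start_offset &
    trace$t_s < onset + cfg$window_end_offset
  n_total <- sum(in_win)
  kept <- in_win & mask
  n_retained <- sum(kept)
  if (n_retained == 0) {
    return(tibble(p_median = NA_real_, p10 = NA_real_, q = 0,
                  d = NA_real_, w = 0, n_total = n_total,
                  n_retained = 0L))
  }
  x <- trace$diameter_mm[kept]
  qs <- quantile(x, c(0.1, 0.5), type = 7, names = FALSE)
  q <- n_retained / n_total
  d <- abs(qs[2] - qs[1])
  tibble(p_median = qs[2], p10 = qs[1], q = q, d = d,
         w = q * exp(-cfg$weight_decay * d),
         n_total = n_total, n_retained = as.integer(n_retained))
}

#' Quality-weighted session estimate of minimal pupil size
#'
#' Combines the per-repeat 10th percentiles of a session (up to five
#' repeats of the same subject/visit/eye/condition) into the robust
#' weighted mean `p_bar = sum(w_i * p10_i) / sum(w_i)`, using only
#' repeats whose quality score strictly exceeds the threshold. If no
#' repeat qualifies the estimate is missing and the status is
#' `"below_quality_threshold"`.
#'
#' @param windows Tibble of per-repeat window statistics (from
#'   [window_estimate()]), with a `repeat_index` column.
#' @param cfg A [filter_config()].
#'
#' @return A list with `p_bar` (mm or `NA`), `status` (`"ok"` or
#'   `"below_quality_threshold"`), `contributing` and `excluded`
#'   tibbles.
#' @export
session_estimate <- function(windows, cfg = filter_config()) {
  if (nrow(windows) == 0) {
    abort("session_estimate: no repeats supplied")
  }
  if (!"repeat_index" %in% names(windows)) {
    windows$repeat_index <- seq_len(nrow(windows))
  }
  qualifies <- windows$q > cfg$quality_threshold & !is.na(windows$p10)
  contributing <- windows[qualifies, , drop = FALSE]
  excluded <- windows[!qualifies, , drop = FALSE]
  excluded$reason <- ifelse(
    is.na(excluded$p10), "no retained samples in window",
    sprintf("q = %.3f not above threshold %.2f", excluded$q,
            cfg$quality_threshold)
  )
  if (nrow(contributing) == 0) {
    return(list(p_bar = NA_real_, status = "below_quality_threshold",
                contributing = contributing,
                excluded = excluded[c("repeat_index", "reason")]))
  }
  p_bar <- sum(contributing$w * contributing$p10) / sum(contributing$w)
  list(p_bar = p_bar, status = "ok", contributing = contributing,
       excluded = excluded[c("repeat_index", "reason")])
}

#' Emulated human-assisted reading of one trace
#'
#' The human-assisted reading marks the minimum pupil size anywhere in
#' the stimulus interval as a single data point. The emulation returns
#' the minimum present diameter over `[stimulus_onset, stimulus_onset +
#' stimulus_duration)` after discarding device-invalid samples and
#' diameters outside the plausibility band (a blink-spike guard), with
#' no Hampel filtering or windowing.
#'
#' @inheritParams hampel_filter
#' @return Minimum diameter in mm, or `NA` when no sample is eligible.
#' @export
human_minimum <- function(trace, cfg = filter_config()) {
  onset <- trace$stimulus_onset_s[1]
  dur <- trace$stimulus_duration_s[1]
  d <- trace$diameter_mm
  ok <- !is.na(d) & trace$device_valid &
    d >= cfg$min_diameter & d <= cfg$max_diameter &
    trace$t_s >= onset & trace$t_s < onset + dur
  if (!any(ok)) {
    return(NA_real_)
  }
  min(d[ok])
}

#' Read one session (automated and emulated human)
#'
#' Applies the full automated chain (Hampel -> validity/step filters ->
#' window statistics -> quality-weighted mean) and the emulated
#' human-assisted reading (per-repeat whole-stimulus minimum, averaged
#' over repeats) to the 1--5 repeats of one
#' subject/visit/eye/condition.
#'
#' @param traces Long tibble of samples containing exactly one
#'   subject/visit/eye/condition (1--5 repeats).
#' @param cfg A [filter_config()].
#'
#' @return A two-row reading-record tibble (`method` = `"automated"`,
#'   `"human"`).
#' @export
read_session <- function(traces, cfg = filter_config()) {
  key <- distinct(traces, across(all_of(setdiff(.trace_key,
                                                "repeat_index"))))
  if (nrow(key) != 1) {
    abort("read_session expects traces from a single subject/visit/eye/condition")
  }
  reps <- split(traces, traces$repeat_index)
  windows <- map_dfr(reps, function(tr) {
    tr <- arrange(tr, .data$t_s)
    mask <- validity_filter(tr, hampel_filter(tr, cfg), cfg)
    est <- window_estimate(tr, mask, cfg)
    est$repeat_index <- tr$repeat_index[1]
    est
  })
  sess <- session_estimate(windows, cfg)
  human_mins <- map_dbl(reps, function(tr) {
    human_minimum(arrange(tr, .data$t_s), cfg)
  })
  human_mm <- if (all(is.na(human_mins))) NA_real_ else {
    mean(human_mins, na.rm = TRUE)
  }
  auto_flags <- paste0(
    "q=", paste(sprintf("%.2f", windows$q), collapse = ","),
    if (nrow(sess$excluded) > 0) {
      paste0("; excluded=",
             paste(sess$excluded$repeat_index, collapse = ","))
    } else "",
    if (sess$status != "ok") "; below_quality_threshold" else ""
  )
  out <- tibble(
    subject_id = key$subject_id, visit = key$visit, eye = key$eye,
    condition = key$condition,
    method = c("automated", "human"),
    pupil_mm = c(sess$p_bar, human_mm),
    n_repeats_used = c(nrow(sess$contributing), sum(!is.na(human_mins))),
    quality_flags = c(auto_flags,
                      "emulated whole-stimulus minimum, mean of repeats")
  )
  attr(out, "windows") <- windows
  out
}

#' Read every session in a trace collection
#'
#' @param traces Long tibble of samples covering any number of sessions.
#' @param cfg A [filter_config()].
#' @param eye Eyes to read (default right only, matching the analysis
#'   convention).
#' @param methods Which reading methods to keep.
#'
#' @return A reading-record tibble, one row per session and method.
#' @export
read_sessions <- function(traces, cfg = filter_config(), eye = "right",
                          methods = c("automated", "human")) {
  traces <- filter(traces, .data$eye %in% !!eye)
  if (nrow(traces) == 0) {
    abort("read_sessions: no traces for the requested eye(s)")
  }
  sessions <- traces %>%
    group_by(across(all_of(setdiff(.trace_key, "repeat_index")))) %>%
    group_split()
  out <- map_dfr(sessions, read_session, cfg = cfg)
  filter(out, .data$method %in% methods)
}
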