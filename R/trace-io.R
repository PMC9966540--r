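# On-disk interchange formats for pupillometer exports.
#
# Trace CSV dialect (long format, one row per sample):
#   subject_id,visit,eye,condition,repeat,lux,sampling_rate_hz,
#   stimulus_onset_s,stimulus_duration_s,t_s,diameter_mm,device_valid
# UTF-8, '.' decimal separator, device_valid in {0,1}, empty diameter_mm
# encodes a missing sample (lost pupil tracking).
#
# Reading CSV dialect (one row per subject-visit-eye-condition-method):
#   subject_id,visit,eye,condition,method,pupil_mm,n_repeats_used,
#   quality_flags

.trace_key <- c("subject_id", "visit", "eye", "condition", "repeat_index")

.trace_file_cols <- c(
  "subject_id", "visit", "eye", "condition", "repeat", "lux",
  "sampling_rate_hz", "stimulus_onset_s", "stimulus_duration_s",
  "t_s", "diameter_mm", "device_valid"
)

.reading_cols <- c(
  "subject_id", "visit", "eye", "condition", "method",
  "pupil_mm", "n_repeats_used", "quality_flags"
)

.reading_key <- c("subject_id", "visit", "eye", "condition", "method")

.condition_lux <- c(mesopic = 4, photopic = 300)

#' Construct a single pupil trace
#'
#' Builds the in-memory (long, tibble) representation of one eye's
#' continuous diameter recording for one examination: 3 s of darkness
#' followed by a sustained light stimulus, sampled at a fixed rate.
#'
#' @param t Sample timestamps in seconds from recording start (strictly
#'   increasing, starting at 0).
#' @param diameter Pupil diameter in mm; `NA` marks samples where the
#'   device lost pupil tracking.
#' @param device_valid Logical validity flag as reported by the
#'   acquisition software (recycled to `length(t)`).
#' @param subject_id,visit,eye,condition,repeat_index Trace identity.
#'   `visit` is `"screening"` or `"baseline"`, `eye` is `"right"` or
#'   `"left"`, `condition` is `"mesopic"` (4 lux) or `"photopic"`
#'   (300 lux), `repeat_index` is 1..5.
#' @param lux Stimulus illuminance; defaults to the value implied by
#'   `condition`.
#' @param sampling_rate Sampling rate in Hz.
#' @param stimulus_onset,stimulus_duration Stimulus timing in seconds
#'   (protocol values 3 and 10).
#'
#' @return A tibble with one row per sample and the trace CSV columns
#'   (with `repeat_index` in place of the reserved word `repeat`).
#' @export
pupil_trace <- function(t, diameter, device_valid = TRUE,
                        subject_id = "S01", visit = "screening",
                        eye = "right", condition = "mesopic",
                        repeat_index = 1L, lux = NULL,
                        sampling_rate = 30, stimulus_onset = 3,
                        stimulus_duration = 10) {
  if (is.null(lux)) {
    lux <- unname(.condition_lux[condition])
  }
  tibble(
    subject_id = subject_id, visit = visit, eye = eye,
    condition = condition, repeat_index = as.integer(repeat_index),
    lux = lux, sampling_rate_hz = sampling_rate,
    stimulus_onset_s = stimulus_onset,
    stimulus_duration_s = stimulus_duration,
    t_s = as.numeric(t), diameter_mm = as.numeric(diameter),
    device_valid = rep_len(as.logical(device_valid), length(t))
  )
}

# One row per trace with a reason string ("" when the trace is valid).
.trace_issues <- function(traces) {
  traces %>%
    group_by(across(all_of(.trace_key))) %>%
    summarise(
      reason = {
        tt <- .data$t_s
        d <- .data$diameter_mm
        onset <- .data$stimulus_onset_s[1]
        dur <- .data$stimulus_duration_s[1]
        rate <- .data$sampling_rate_hz[1]
        lux <- .data$lux[1]
        cond <- .data$condition[1]
        probs <- character()
        if (any(diff(tt) <= 0)) {
          probs <- c(probs, "timestamps not strictly increasing")
        }
        if (any(!is.finite(d[!is.na(d)])) || any(d <= 0, na.rm = TRUE)) {
          probs <- c(probs, "non-positive or non-finite diameter")
        }
        if (min(tt) > 1e-9 ||
            max(tt) < onset + dur - 1 / rate - 1e-6) {
          probs <- c(probs, "samples do not span [0, onset + duration)")
        }
        if (!cond %in% names(.condition_lux) ||
            !isTRUE(all.equal(unname(.condition_lux[cond]), lux))) {
          probs <- c(probs, "condition/lux mismatch")
        }
        if (!.data$repeat_index[1] %in% 1:5) {
          probs <- c(probs, "repeat_index outside 1..5")
        }
        paste(probs, collapse = "; ")
      },
      .groups = "drop"
    )
}

#' Validate pupil traces
#'
#' Checks every trace (one `subject_id`/`visit`/`eye`/`condition`/
#' `repeat_index` group) against the structural invariants: strictly
#' increasing timestamps, finite positive diameters where present,
#' coverage of the full recording span, condition/lux consistency and
#' repeat index in 1..5.
#'
#' @param traces Long tibble of samples as produced by [pupil_trace()] or
#'   [read_traces()].
#' @param strict If `TRUE`, any violation is an error; if `FALSE`,
#'   offending traces are dropped with a warning.
#'
#' @return The (possibly filtered) traces, sorted by key and timestamp.
#' @export
validate_traces <- function(traces, strict = TRUE) {
  traces <- arrange(traces, across(all_of(.trace_key)), .data$t_s)
  if (nrow(traces) == 0) {
    return(traces)
  }
  issues <- .trace_issues(traces)
  bad <- filter(issues, .data$reason != "")
  if (nrow(bad) > 0) {
    msg <- paste0(
      bad$subject_id, "/", bad$visit, "/", bad$eye, "/", bad$condition,
      "/rep", bad$repeat_index, ": ", bad$reason
    )
    if (strict) {
      abort(c("invalid pupil trace(s):", head(msg, 10)),
            class = "pupilagree_integrity_error")
    }
    warn(c("dropping invalid pupil trace(s):", head(msg, 10)))
    traces <- dplyr::anti_join(traces, select(bad, -"reason"),
                               by = .trace_key)
  }
  traces
}

#' Read pupil traces from the trace CSV dialect
#'
#' @param path Path to a trace CSV file.
#' @param strict Passed to [validate_traces()]: errors on invariant
#'   violations when `TRUE`, drops offending traces with a warning when
#'   `FALSE`.
#'
#' @return A long tibble of samples, one trace per
#'   subject/visit/eye/condition/repeat group, sorted by timestamp.
#' @export
read_traces <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("trace file not found: ", path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing <- setdiff(.trace_file_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("trace file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pupilagree_format_error")
  }
  df <- df %>%
    rename(repeat_index = "repeat") %>%
    mutate(
      repeat_index = as.integer(.data$repeat_index),
      lux = as.numeric(.data$lux),
      sampling_rate_hz = as.numeric(.data$sampling_rate_hz),
      stimulus_onset_s = as.numeric(.data$stimulus_onset_s),
      stimulus_duration_s = as.numeric(.data$stimulus_duration_s),
      t_s = as.numeric(.data$t_s),
      diameter_mm = as.numeric(.data$diameter_mm),
      device_valid = as.numeric(.data$device_valid) == 1
    )
  validate_traces(df, strict = strict)
}

#' Write pupil traces to the trace CSV dialect
#'
#' Missing diameters are serialized as empty fields; `device_valid` as
#' 0/1. [read_traces()] composed with `write_traces()` reproduces the
#' in-memory data exactly.
#'
#' @param traces Long tibble of samples (see [pupil_trace()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  out <- traces %>%
    arrange(across(all_of(.trace_key)), .data$t_s) %>%
    mutate(device_valid = as.integer(.data$device_valid)) %>%
    rename("repeat" = "repeat_index") %>%
    select(all_of(.trace_file_cols))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read or write per-session reading records
#'
#' A reading record is one minimal-pupil-size estimate for one
#' subject/visit/eye/condition and reading method (`"automated"` or
#' `"human"`). `pupil_mm` may be missing when every repeat fell below the
#' quality threshold, in which case `n_repeats_used` is 0.
#'
#' @param path CSV file path.
#' @param strict If `TRUE`, duplicate keys, implausible diameters
#'   (outside 2--9 mm) and inconsistent missing/`n_repeats_used` states
#'   are errors; if `FALSE`, offending records are dropped with a
#'   warning.
#'
#' @return `read_readings()` returns a tibble of reading records;
#'   `write_readings()` returns `path` invisibly.
#' @export
read_readings <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("reading file not found: ", path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing <- setdiff(.reading_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("reading file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pupilagree_format_error")
  }
  df <- df %>%
    mutate(
      pupil_mm = as.numeric(.data$pupil_mm),
      n_repeats_used = as.integer(.data$n_repeats_used),
      quality_flags = dplyr::coalesce(.data$quality_flags, "")
    ) %>%
    select(all_of(.reading_cols))
  validate_readings(df, strict = strict)
}

#' @rdname read_readings
#' @param records Tibble of reading records.
#' @export
write_readings <- function(records, path) {
  validate_readings(records, strict = TRUE)
  readr::write_csv(select(records, all_of(.reading_cols)), path, na = "")
  invisible(path)
}

#' @rdname read_readings
#' @param records Tibble of reading records.
#' @export
validate_readings <- function(records, strict = TRUE) {
  dup <- records %>%
    dplyr::count(across(all_of(.reading_key))) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(c("duplicate reading record key(s):",
            head(paste(dup$subject_id, dup$visit, dup$eye, dup$condition,
                       dup$method, sep = "/"), 10)),
          class = "pupilagree_integrity_error")
  }
  bad_range <- !is.na(records$pupil_mm) &
    (records$pupil_mm < 2 | records$pupil_mm > 9)
  bad_zero <- (records$n_repeats_used == 0) != is.na(records$pupil_mm)
  bad <- bad_range | bad_zero
  if (any(bad)) {
    msg <- paste0(records$subject_id[bad], "/", records$visit[bad], "/",
                  records$condition[bad], "/", records$method[bad],
                  ifelse(bad_range[bad], ": pupil_mm outside [2, 9] mm",
                         ": n_repeats_used inconsistent with missing pupil_mm"))
    if (strict) {
      abort(c("invalid reading record(s):", head(msg, 10)),
            class = "pupilagree_integrity_error")
    }
    warn(c("dropping invalid reading record(s):", head(msg, 10)))
    records <- records[!bad, , drop = FALSE]
  }
  records
}
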