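# Synthetic pupillary light reflex generator: piecewise-exponential
# trajectory (baseline -> phasic constriction -> pupillary escape ->
# optional latent constriction), Gaussian measurement noise, and blink
# artifacts (runs of missing/invalid samples flanked by sub-2 mm
# spikes). A fixture with the statistical structure the analysis
# assumes, not a physiological model.

#' Trace generator parameters
#'
#' @param baseline Dark-adapted diameter, mm.
#' @param latency Onset-to-constriction delay, s.
#' @param phasic_min Trough of the initial phasic constriction, mm
#'   (also the plateau the 2--4 s analysis window sits on when the
#'   escape is delayed past the window).
#' @param time_to_min Time from stimulus onset to the trough, s.
#' @param escape_amplitude Re-dilation from the trough toward the
#'   sustained plateau, mm (pupillary escape; larger under mesopic
#'   light).
#' @param escape_tau Escape time constant, s.
#' @param escape_delay Delay between reaching the trough and the start
#'   of the escape, s (0 = escape starts at the trough).
#' @param latent_constriction Optional named vector
#'   `c(time_s =, depth_mm =, width_s =)` describing a late
#'   re-constriction: the trace dips smoothly to the absolute level
#'   `depth_mm` at `time_s` (Gaussian bump, default width 0.35 s).
#' @param noise_sd Additive Gaussian measurement noise, mm.
#' @param blink_rate Blink events per second (Poisson process).
#' @param blink_duration Blink duration, s; blink samples are missing
#'   and device-invalid, flanked by short sub-2 mm spikes.
#' @param seed Integer seed; identical parameters and seed reproduce
#'   the trace exactly, including blink placement.
#'
#' @return List of class `"trace_params"`.
#' @export
trace_params <- function(baseline = 7.4, latency = 0.25,
                         phasic_min = 4.0, time_to_min = 2.0,
                         escape_amplitude = 0.8, escape_tau = 0.6,
                         escape_delay = 0,
                         latent_constriction = NULL,
                         noise_sd = 0.05, blink_rate = 0.1,
                         blink_duration = 0.15, seed = 1L) {
  p <- list(baseline = baseline, latency = latency,
            phasic_min = phasic_min, time_to_min = time_to_min,
            escape_amplitude = escape_amplitude, escape_tau = escape_tau,
            escape_delay = escape_delay,
            latent_constriction = latent_constriction,
            noise_sd = noise_sd, blink_rate = blink_rate,
            blink_duration = blink_duration, seed = as.integer(seed))
  if (!(phasic_min > 2 && phasic_min < baseline && baseline <= 9)) {
    abort("trace_params requires 2 < phasic_min < baseline <= 9")
  }
  if (escape_amplitude < 0 || escape_tau <= 0 || noise_sd < 0 ||
      blink_rate < 0 || latency < 0 || latency >= time_to_min) {
    abort("invalid trace_params: check escape/noise/blink/latency values")
  }
  if (!is.null(latent_constriction)) {
    lc <- latent_constriction
    if (!all(c("time_s", "depth_mm") %in% names(lc))) {
      abort("latent_constriction needs named elements time_s and depth_mm")
    }
    if (lc[["depth_mm"]] < 2) {
      abort("latent_constriction depth_mm must stay within [2, 9] mm")
    }
  }
  structure(p, class = "trace_params")
}

# Deterministic mean trajectory (no noise, no blinks).
pupil_trajectory <- function(t, p, stimulus_onset = 3) {
  con_start <- stimulus_onset + p$latency
  t_min <- stimulus_onset + p$time_to_min
  esc_start <- t_min + p$escape_delay
  v <- rep(p$baseline, length(t))
  # scaled exponential approach hitting phasic_min exactly at t_min;
  # k = 2 keeps the peak constriction velocity near 2.3 * depth / time,
  # well under the ~15 mm/s the step filter treats as implausible
  k <- 2
  s <- (t - con_start) / (t_min - con_start)
  con <- t >= con_start & t < t_min
  v[con] <- p$phasic_min + (p$baseline - p$phasic_min) *
    (exp(-k * s[con]) - exp(-k)) / (1 - exp(-k))
  v[t >= t_min] <- p$phasic_min
  esc <- t >= esc_start
  v[esc] <- p$phasic_min + p$escape_amplitude *
    (1 - exp(-(t[esc] - esc_start) / p$escape_tau))
  if (!is.null(p$latent_constriction)) {
    lc <- p$latent_constriction
    width <- if ("width_s" %in% names(lc)) lc[["width_s"]] else 0.35
    centre_level <- p$phasic_min
    if (lc[["time_s"]] >= esc_start) {
      centre_level <- p$phasic_min + p$escape_amplitude *
        (1 - exp(-(lc[["time_s"]] - esc_start) / p$escape_tau))
    }
    amp <- centre_level - lc[["depth_mm"]]
    if (amp < 0) {
      abort("latent_constriction depth_mm lies above the trajectory")
    }
    v <- v - amp * exp(-((t - lc[["time_s"]]) / width)^2)
  }
  v
}

#' Simulate one pupil trace
#'
#' Samples the deterministic trajectory at the given rate over
#' `[0, stimulus_onset + stimulus_duration)`, adds Gaussian noise, and
#' overlays blink artifacts: runs of missing, device-invalid samples
#' flanked by brief sub-2 mm spikes (so both the validity and the
#' plausibility-band filters are exercised). Fully deterministic given
#' `p$seed`.
#'
#' @param p A [trace_params()] object.
#' @param condition,subject_id,visit,eye,repeat_index Trace identity
#'   (see [pupil_trace()]).
#' @param sampling_rate Hz (default 30).
#' @param stimulus_onset,stimulus_duration Protocol timing, s.
#'
#' @return A single-trace tibble.
#' @export
simulate_trace <- function(p, condition = "mesopic", subject_id = "S01",
                           visit = "screening", eye = "right",
                           repeat_index = 1L, sampling_rate = 30,
                           stimulus_onset = 3, stimulus_duration = 10) {
  total <- stimulus_onset + stimulus_duration
  n <- round(total * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  v <- pupil_trajectory(t, p, stimulus_onset)
  if (any(v <= 0 | v >= 10)) {
    abort("trace_params produce a trajectory outside (0, 10) mm")
  }
  diameter <- v
  valid <- rep(TRUE, n)
  withr::with_seed(p$seed, {
    if (p$noise_sd > 0) {
      diameter <- diameter + rnorm(n, 0, p$noise_sd)
    }
    n_blinks <- rpois(1, p$blink_rate * total)
    if (n_blinks > 0) {
      starts <- sort(runif(n_blinks, 0, total - p$blink_duration))
      for (b in starts) {
        idx <- which(t >= b & t < b + p$blink_duration)
        if (length(idx) == 0) next
        diameter[idx] <- NA_real_
        valid[idx] <- FALSE
        flank <- c(min(idx) - 1L, max(idx) + 1L)
        flank <- flank[flank >= 1 & flank <= n]
        diameter[flank] <- runif(length(flank), 1.0, 1.9)
      }
    }
  })
  diameter[!is.na(diameter)] <- pmax(diameter[!is.na(diameter)], 0.1)
  pupil_trace(t, diameter, device_valid = valid,
              subject_id = subject_id, visit = visit, eye = eye,
              condition = condition, repeat_index = repeat_index,
              sampling_rate = sampling_rate,
              stimulus_onset = stimulus_onset,
              stimulus_duration = stimulus_duration)
}

#' Named trace presets
#'
#' `"figure1"`: deep mesopic constriction (7.5 -> 3.4 mm) with a strong
#' escape starting at the trough, no latent event -- illustrates the
#' inherent 10th-percentile vs single-point difference between reading
#' methods. `"figure2"`: constriction to a 4.7 mm plateau spanning the
#' 2--4 s window, delayed escape, and a noise-free latent constriction
#' to 4.1 mm at 10.5 s -- the automated reading sees the plateau, the
#' human-assisted reading the latent minimum.
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned parameters.
#' @return A [trace_params()] object.
#' @export
trace_preset <- function(name = c("figure1", "figure2"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    figure1 = trace_params(
      baseline = 7.5, latency = 0.3, phasic_min = 3.4, time_to_min = 2.5,
      escape_amplitude = 1.6, escape_tau = 0.8, escape_delay = 0,
      noise_sd = 0.05, blink_rate = 0.1, seed = seed
    ),
    figure2 = trace_params(
      baseline = 7.7, latency = 0.3, phasic_min = 4.7, time_to_min = 2.0,
      escape_amplitude = 0.9, escape_tau = 0.5, escape_delay = 2.0,
      latent_constriction = c(time_s = 10.5, depth_mm = 4.1,
                              width_s = 0.35),
      noise_sd = 0, blink_rate = 0, seed = seed
    )
  )
}

#' Simulate one session (five tolerability-checked repeats)
#'
#' Draws `k` per-repeat minima around the subject's true minimal pupil
#' size (Gaussian with `repeat_sd`, redrawn up to `max_tries` times
#' until their spread is at most `tolerability_range`, emulating the
#' device's acceptance rule) and generates one trace per repeat. The
#' per-repeat trace places the 2--4 s window plateau at
#' `minimum * method_bias` and a latent constriction dipping to the
#' drawn minimum, so the automated reading targets the plateau and the
#' human-assisted reading the true minimum.
#'
#' @param true_min Subject's true minimal pupil size, mm.
#' @param condition Light condition (drives the lux field and the
#'   escape preset: larger escape under mesopic light).
#' @param template A [trace_params()] supplying trajectory/noise/blink
#'   defaults for the session.
#' @param method_bias Multiplicative automated-vs-human factor.
#' @param repeat_sd Within-session SD of per-repeat minima, mm.
#' @param tolerability_range Maximum allowed spread of the `k` minima,
#'   mm (device protocol: 1.0).
#' @param k Number of repeats (protocol: 5).
#' @param max_tries Rejection-sampling cap for the tolerability rule.
#' @param seed Integer seed.
#' @param subject_id,visit,eye Trace identity.
#'
#' @return List with `traces` (bound tibble) and `minima` (the drawn
#'   per-repeat minima).
#' @export
simulate_session <- function(true_min, condition = "mesopic",
                             template = trace_params(),
                             method_bias = 1, repeat_sd = 0.15,
                             tolerability_range = 1.0, k = 5,
                             max_tries = 100, seed = 1L,
                             subject_id = "S01", visit = "screening",
                             eye = "right") {
  draws <- withr::with_seed(seed, {
    minima <- NULL
    for (i in seq_len(max_tries)) {
      cand <- rnorm(k, true_min, repeat_sd)
      cand <- pmin(pmax(cand, 2.15), 8.6)
      if (diff(range(cand)) <= tolerability_range) {
        minima <- cand
        break
      }
    }
    if (is.null(minima)) {
      abort(sprintf(paste0("tolerability range %.2f mm not met in %d ",
                           "tries (true_min = %.2f, repeat_sd = %.2f)"),
                    tolerability_range, max_tries, true_min, repeat_sd))
    }
    list(minima = minima,
         seeds = sample.int(.Machine$integer.max - 1, k))
  })
  esc <- if (condition == "mesopic") {
    c(amplitude = template$escape_amplitude, tau = template$escape_tau)
  } else {
    # photopic light sustains the constriction: weak escape
    c(amplitude = template$escape_amplitude * 0.3,
      tau = template$escape_tau)
  }
  traces <- map_dfr(seq_len(k), function(i) {
    m <- draws$minima[i]
    plateau <- min(m * method_bias, template$baseline - 0.5)
    # constriction time scales with depth (mean velocity ~3 mm/s) so
    # steep constrictions stay physiological; escape is delayed past
    # the 2-4 s analysis window so the window sits on the plateau
    time_to_min <- template$latency + (template$baseline - plateau) / 3
    p <- trace_params(
      baseline = template$baseline, latency = template$latency,
      phasic_min = plateau, time_to_min = time_to_min,
      escape_amplitude = esc[["amplitude"]], escape_tau = esc[["tau"]],
      escape_delay = max(0, 4.3 - time_to_min),
      latent_constriction = c(time_s = 10.5, depth_mm = m,
                              width_s = 0.35),
      noise_sd = template$noise_sd, blink_rate = template$blink_rate,
      blink_duration = template$blink_duration, seed = draws$seeds[i]
    )
    simulate_trace(p, condition = condition, subject_id = subject_id,
                   visit = visit, eye = eye, repeat_index = i)
  })
  list(traces = traces, minima = draws$minima)
}

#' Cohort generator parameters
#'
#' Defaults emulate the study conditions: 43 subjects, mesopic minimal
#' pupil sizes 4.12 (0.70) mm and photopic 2.73 (0.29) mm across
#' subjects, between-visit SDs 0.454 mm (mesopic) and 0.122 mm
#' (photopic) -- the SDs implied by agreement coefficients of 0.89 and
#' 0.24 mm via coefficient = 1.96 * SD -- and a multiplicative
#' automated-vs-human reading bias of 1.023 (mesopic) / 1.011
#' (photopic).
#'
#' @param n_subjects Number of subjects.
#' @param cond_mean,cond_sd Named (mesopic/photopic) across-subject mean
#'   and SD of true minimal pupil size, mm.
#' @param between_visit_sd Named SD of the visit-2 minus visit-1 true
#'   difference, mm. Visits deviate independently from the subject's
#'   latent size with SD `between_visit_sd / sqrt(2)` each, so the two
#'   visits have equal variance (no structural correlation between
#'   differences and averages) and their difference has the stated SD.
#' @param method_bias Named multiplicative automated/human factor on
#'   top of the intrinsic percentile-vs-minimum reading asymmetry. The
#'   photopic default is 1 because the intrinsic asymmetry alone
#'   accounts for the small photopic between-method gap.
#' @param repeat_sd Named within-session SD of per-repeat minima, mm.
#' @param tolerability_range Device acceptance rule, mm.
#' @param noise_sd,blink_rate Trace-level noise and blink parameters.
#' @param seed Integer master seed.
#'
#' @return List of class `"cohort_params"`.
#' @export
cohort_params <- function(n_subjects = 43,
                          cond_mean = c(mesopic = 4.12, photopic = 2.73),
                          cond_sd = c(mesopic = 0.70, photopic = 0.29),
                          between_visit_sd = c(mesopic = 0.454,
                                               photopic = 0.122),
                          method_bias = c(mesopic = 1.023,
                                          photopic = 1.0),
                          repeat_sd = c(mesopic = 0.15,
                                        photopic = 0.08),
                          tolerability_range = 1.0,
                          noise_sd = 0.05, blink_rate = 0.1,
                          seed = 1L) {
  if (n_subjects < 3) {
    abort("cohort_params requires n_subjects >= 3")
  }
  if (any(c(cond_sd, between_visit_sd, repeat_sd) < 0)) {
    abort("cohort_params SDs must be non-negative")
  }
  structure(
    list(n_subjects = n_subjects, cond_mean = cond_mean,
         cond_sd = cond_sd, between_visit_sd = between_visit_sd,
         method_bias = method_bias, repeat_sd = repeat_sd,
         tolerability_range = tolerability_range, noise_sd = noise_sd,
         blink_rate = blink_rate, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' Simulate a two-visit cohort
#'
#' For every subject and condition, draws a true minimal pupil size
#' (truncated Gaussian across subjects), a visit-2 value offset by a
#' Gaussian between-visit change, and a dark baseline diameter, then
#' generates five tolerability-checked repeats per
#' subject/visit/condition via [simulate_session()]. The ground-truth
#' table records every latent variable and is never consulted by the
#' reading pipeline.
#'
#' @param cp A [cohort_params()] object.
#' @param eyes Eyes to generate (default right only).
#'
#' @return List with `traces` (long sample tibble for all sessions) and
#'   `truth` (one row per subject/visit/condition with the true and
#'   per-repeat minima).
#' @export
simulate_cohort <- function(cp = cohort_params(), eyes = "right") {
  conditions <- names(cp$cond_mean)
  subjects <- sprintf("S%03d", seq_len(cp$n_subjects))
  plan <- withr::with_seed(cp$seed, {
    rows <- list()
    for (s in subjects) {
      base <- min(max(rnorm(1, 7.4, 0.4), 6.2), 8.9)
      for (cond in conditions) {
        mu <- rnorm(1, cp$cond_mean[[cond]], cp$cond_sd[[cond]])
        # stationary visit deviations: equal variance at both visits,
        # difference SD = between_visit_sd
        dev <- rnorm(2, 0, cp$between_visit_sd[[cond]] / sqrt(2))
        t1 <- min(max(mu + dev[1], 2.4), base - 1.2)
        t2 <- min(max(mu + dev[2], 2.4), base - 1.2)
        for (v in c("screening", "baseline")) {
          rows[[length(rows) + 1]] <- tibble(
            subject_id = s, visit = v, condition = cond,
            baseline_mm = base,
            true_min = if (v == "screening") t1 else t2,
            seed = sample.int(.Machine$integer.max - 1, 1)
          )
        }
      }
    }
    bind_rows(rows)
  })
  out <- map(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    template <- trace_params(
      baseline = row$baseline_mm, latency = 0.25,
      phasic_min = min(row$true_min, row$baseline_mm - 1),
      time_to_min = 1.8,
      escape_amplitude = 0.9, escape_tau = 0.6, escape_delay = 2.4,
      noise_sd = cp$noise_sd, blink_rate = cp$blink_rate,
      seed = row$seed
    )
    eye_runs <- map(eyes, function(e) {
      simulate_session(
        true_min = row$true_min, condition = row$condition,
        template = template,
        method_bias = cp$method_bias[[row$condition]],
        repeat_sd = cp$repeat_sd[[row$condition]],
        tolerability_range = cp$tolerability_range,
        seed = row$seed, subject_id = row$subject_id,
        visit = row$visit, eye = e
      )
    })
    list(traces = bind_rows(map(eye_runs, "traces")),
         minima = eye_runs[[1]]$minima)
  })
  truth <- plan
  truth$repeat_minima <- vapply(out, function(o) {
    paste(sprintf("%.4f", o$minima), collapse = ";")
  }, character(1))
  list(traces = bind_rows(map(out, "traces")), truth = truth)
}

#' Write or read a cohort configuration as YAML
#'
#' Serializes the resolved generator parameters alongside simulated
#' datasets so a run can be reproduced from its output directory.
#'
#' @param cp A [cohort_params()] object.
#' @param path YAML file path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a [cohort_params()] object.
#' @export
write_cohort_config <- function(cp, path) {
  x <- unclass(cp)
  x[c("cond_mean", "cond_sd", "between_visit_sd", "method_bias",
      "repeat_sd")] <-
    lapply(x[c("cond_mean", "cond_sd", "between_visit_sd",
               "method_bias", "repeat_sd")], as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("cond_mean", "cond_sd", "between_visit_sd",
               "method_bias", "repeat_sd")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  do.call(cohort_params, x)
}

#' Simulate paired session readings directly
#'
#' Reading-level counterpart of the trace generator for statistical
#' recovery studies: per-subject true sizes are Gaussian across
#' subjects, side `b` observes them with session-estimate noise and
#' side `a` observes `ratio_bias` times them with the same noise. With
#' `ratio_bias = 1` and `delta_sd > 0` the pairs mimic a two-visit
#' comparison with between-visit SD `delta_sd`.
#'
#' @param n Number of subjects.
#' @param mean,sd Across-subject distribution of the true size, mm.
#' @param ratio_bias Multiplicative bias of side `a` relative to `b`.
#' @param delta_sd SD of the true between-side change `a - b`, split
#'   evenly over the two sides (each deviates from the shared truth
#'   with SD `delta_sd / sqrt(2)`), mm.
#' @param noise_sd Session-estimate noise per side, mm.
#' @param seed Integer seed.
#'
#' @return Paired-measurement tibble (`subject_id`, `a`, `b`).
#' @export
simulate_paired_readings <- function(n, mean = 4.12, sd = 0.70,
                                     ratio_bias = 1, delta_sd = 0,
                                     noise_sd = 0.02, seed = 1L) {
  withr::with_seed(seed, {
    truth <- rnorm(n, mean, sd)
    a <- ratio_bias * (truth + rnorm(n, 0, delta_sd / sqrt(2))) +
      rnorm(n, 0, noise_sd)
    b <- truth + rnorm(n, 0, delta_sd / sqrt(2)) +
      rnorm(n, 0, noise_sd)
    out <- tibble(subject_id = sprintf("S%03d", seq_len(n)),
                  a = a, b = b)
    attr(out, "labels") <- c("a", "b")
    out
  })
}
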