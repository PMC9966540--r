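cfg <- filter_config()

test_that("Hampel pass matches the brute-force oracle on jittered traces", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 120
    t <- (seq_len(n) - 1) / 30
    x <- 5 + rnorm(n, 0, 0.05)
    x[sample(n, 3)] <- 5 + runif(3, 0.5, 3)   # outliers of mixed size
    x[sample(n, 4)] <- NA                     # lost tracking
    tr <- pupil_trace(t, x)
    expect_identical(hampel_filter(tr, cfg), bf_hampel(t, x))
  }
})

test_that("Hampel removes by the 1.5 mm cap and by 3 x MAD, whichever bites", {
  tr <- flat_trace(overrides = c("100" = 7.2))
  mask <- hampel_filter(tr, cfg)
  expect_false(mask[100])          # deviation 2.2 > 1.5 mm cap
  expect_true(all(mask[-100]))     # constant elsewhere: zero deviation

  # tiny jitter: the MAD scale is a few hundredths of a mm, so 3 S
  # catches a 0.8 mm deviation that the 1.5 mm absolute cap would let
  # through
  set.seed(1)
  n <- 60
  x <- 5 + rnorm(n, 0, 0.03)
  x[30] <- 5.8
  t <- (seq_len(n) - 1) / 30
  tr <- pupil_trace(t, x)
  w <- x[abs(t - t[30]) <= 0.7 + 1e-9]
  s <- 1.4826 * median(abs(w - median(w)))
  expect_gt(s, 0.01)
  expect_lt(3 * s, 0.8)
  mask <- hampel_filter(tr, cfg)
  expect_identical(mask, bf_hampel(t, x))
  expect_false(mask[30])
  expect_gte(sum(mask), 55)
})

test_that("single-sample windows retain the sample and empty traces error", {
  tr <- pupil_trace(c(0, 5, 10), c(5, 3, 6))  # sparse: windows of one
  expect_true(all(hampel_filter(tr, cfg)))
  expect_error(hampel_filter(tr[0, ], cfg), "empty")
  all_na <- pupil_trace(0:2, rep(NA_real_, 3))
  expect_error(hampel_filter(all_na, cfg), "no present diameters")
})

test_that("validity filter applies range, device and step rules", {
  tr <- flat_trace(overrides = c("50" = 1.9, "60" = 9.4))
  tr$device_valid[70] <- FALSE
  tr$diameter_mm[80] <- NA
  mask <- validity_filter(tr, rep(TRUE, nrow(tr)), cfg)
  expect_false(any(mask[c(50, 60, 70, 80)]))
  expect_true(all(mask[-c(50, 60, 70, 80)]))

  # step rule anchored to the last retained point: 5.0, 5.6, 5.1
  tr <- pupil_trace((0:2) / 30, c(5.0, 5.6, 5.1))
  mask <- validity_filter(tr, rep(TRUE, 3), cfg)
  expect_identical(mask, c(TRUE, FALSE, TRUE))
  # raw-anchored variant removes 5.6 and also re-admits 5.1 here
  # (|5.1 - 5.6| = 0.5 is allowed); a genuine jump then persists
  raw_cfg <- filter_config(step_anchor = "raw")
  expect_identical(validity_filter(tr, rep(TRUE, 3), raw_cfg),
                   c(TRUE, FALSE, TRUE))
  jump <- pupil_trace((0:2) / 30, c(5.0, 6.2, 6.2))
  expect_identical(validity_filter(jump, rep(TRUE, 3), cfg),
                   c(TRUE, FALSE, FALSE))
  expect_identical(validity_filter(jump, rep(TRUE, 3), raw_cfg),
                   c(TRUE, FALSE, TRUE))
})

test_that("window percentiles match a brute-force sort-and-interpolate oracle", {
  set.seed(99)
  for (rep in 1:20) {
    m <- sample(3:50, 1)
    vals <- round(runif(m, 3, 6), 3)
    n <- 390
    tr <- flat_trace()
    idx <- window_idx(tr)[seq_len(m)]
    tr$diameter_mm[idx] <- vals
    mask <- rep(FALSE, n)
    mask[idx] <- TRUE
    est <- window_estimate(tr, mask, cfg)
    expect_equal(est$p10, bf_quantile(vals, 0.1), tolerance = 1e-12)
    expect_equal(est$p_median, bf_quantile(vals, 0.5), tolerance = 1e-12)
    expect_equal(est$q, m / 60)
  }
})

test_that("window statistics: constant window, strict q threshold, weights", {
  tr <- flat_trace(4.0)
  mask <- rep(TRUE, nrow(tr))
  est <- window_estimate(tr, mask, cfg)
  expect_equal(est$n_total, 60L)
  expect_equal(c(est$p_median, est$p10, est$d), c(4, 4, 0))
  expect_equal(c(est$q, est$w), c(1, 1))

  # exactly half retained: q = 0.5 fails the strict q > 0.5 rule
  half <- mask
  half[window_idx(tr)[1:30]] <- FALSE
  est_half <- window_estimate(tr, half, cfg)
  expect_equal(est_half$q, 0.5)
  sess <- session_estimate(
    dplyr::mutate(est_half, repeat_index = 1L), cfg)
  expect_identical(sess$status, "below_quality_threshold")
  expect_true(is.na(sess$p_bar))

  # p_median 4.2, p10 4.0 -> d = 0.2, w = q * exp(-0.4)
  tr2 <- flat_trace(4.2)
  tr2$diameter_mm[window_idx(tr2)[1:7]] <- 4.0
  est2 <- window_estimate(tr2, rep(TRUE, nrow(tr2)), cfg)
  expect_equal(c(est2$p_median, est2$p10), c(4.2, 4.0))
  expect_equal(est2$w, 1 * exp(-2 * 0.2), tolerance = 1e-12)
  expect_equal(est2$w, 0.67032004603564, tolerance = 1e-10)

  # no retained samples: q = 0, missing percentiles, w = 0
  est0 <- window_estimate(tr, rep(FALSE, nrow(tr)), cfg)
  expect_equal(c(est0$q, est0$w), c(0, 0))
  expect_true(is.na(est0$p10))
})

test_that("weight decays monotonically in spread and equals q at d = 0", {
  for (q in c(0.6, 0.8, 1)) {
    d <- seq(0, 2, by = 0.05)
    w <- q * exp(-cfg$weight_decay * d)
    expect_true(all(diff(w) < 0))
    expect_equal(w[1], q)
    # same law as produced by window_estimate
    tr <- flat_trace(4.5)
    est <- window_estimate(tr, rep(TRUE, nrow(tr)), cfg)
    expect_equal(est$w, est$q * exp(-cfg$weight_decay * est$d))
  }
})

test_that("session estimate is the quality-weighted mean, bounded by its inputs", {
  win <- tibble::tibble(repeat_index = 1:2, p10 = c(3, 4),
                        p_median = c(3, 4), q = c(1, 1), d = c(0, 0),
                        w = c(1, 0.5), n_total = 60L, n_retained = 60L)
  sess <- session_estimate(win, cfg)
  expect_equal(sess$p_bar, (3 * 1 + 4 * 0.5) / 1.5, tolerance = 1e-12)
  expect_equal(sess$p_bar, 10 / 3, tolerance = 1e-12)

  # identical inputs pass through
  same <- dplyr::mutate(win, p10 = 3, w = 1)
  expect_equal(session_estimate(same, cfg)$p_bar, 3)

  # all repeats at q = 0.4: below threshold, estimate missing
  low <- dplyr::mutate(win, q = 0.4)
  out <- session_estimate(low, cfg)
  expect_identical(out$status, "below_quality_threshold")
  expect_true(is.na(out$p_bar))
  expect_identical(nrow(out$contributing), 0L)
  expect_error(session_estimate(win[0, ], cfg), "no repeats")

  # boundedness property on random sessions
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    wins <- tibble::tibble(repeat_index = seq_len(k),
                           p10 = runif(k, 3, 5),
                           q = runif(k, 0.55, 1))
    wins$d <- runif(k, 0, 0.5)
    wins$w <- wins$q * exp(-2 * wins$d)
    sess <- session_estimate(wins, cfg)
    expect_gte(sess$p_bar, min(wins$p10))
    expect_lte(sess$p_bar, max(wins$p10))
  }
})

test_that("human reading takes the whole-stimulus minimum, guarding blinks", {
  # monotone constriction reaching 3.4 mm
  tr <- simulate_trace(trace_params(baseline = 7.5, phasic_min = 3.4,
                                    time_to_min = 2.5,
                                    escape_amplitude = 0, noise_sd = 0,
                                    blink_rate = 0, seed = 1))
  expect_equal(human_minimum(tr, cfg), 3.4, tolerance = 1e-12)

  # a 1.2 mm blink spike is ignored; pre-stimulus values are ignored
  tr2 <- flat_trace(5)
  tr2$diameter_mm[200] <- 1.2
  tr2$diameter_mm[250] <- 4.6
  tr2$diameter_mm[10] <- 3.0    # before stimulus onset
  expect_equal(human_minimum(tr2, cfg), 4.6)

  # device-invalid minima are ignored; nothing eligible -> NA
  tr2$device_valid[250] <- FALSE
  expect_equal(human_minimum(tr2, cfg), 5)
  none <- flat_trace(5, device_valid = FALSE)
  expect_true(is.na(human_minimum(none, cfg)))
})

test_that("filters are transparent on noise-free artifact-free traces", {
  for (p in list(trace_params(noise_sd = 0, blink_rate = 0, seed = 1),
                 trace_params(baseline = 8.5, phasic_min = 2.6,
                              time_to_min = 2.4, noise_sd = 0,
                              blink_rate = 0, seed = 2))) {
    tr <- simulate_trace(p)
    mask <- validity_filter(tr, hampel_filter(tr, cfg), cfg)
    expect_true(all(mask))
  }
})

test_that("reading a clean plateau session recovers the target with both methods", {
  p <- trace_params(baseline = 7.2, phasic_min = 3.0, time_to_min = 1.8,
                    escape_amplitude = 0, noise_sd = 0, blink_rate = 0,
                    seed = 3)
  traces <- purrr::map_dfr(1:5, function(r) {
    simulate_trace(p, repeat_index = r)
  })
  rec <- read_session(traces, cfg)
  expect_equal(rec$pupil_mm[rec$method == "automated"], 3.0,
               tolerance = 1e-9)
  expect_equal(rec$pupil_mm[rec$method == "human"], 3.0,
               tolerance = 1e-9)
  expect_identical(rec$n_repeats_used, c(5L, 5L))
})

test_that("pupillary escape inside the window pushes automated above human", {
  read_gap <- function(amplitude) {
    p <- trace_params(baseline = 7.4, phasic_min = 3.6, time_to_min = 2,
                      escape_amplitude = amplitude, escape_tau = 1.2,
                      escape_delay = 0, noise_sd = 0, blink_rate = 0,
                      seed = 4)
    tr <- simulate_trace(p)
    rec <- read_session(tr, cfg)
    diff(rev(rec$pupil_mm)) # automated - human
  }
  gaps <- vapply(c(0, 0.4, 0.8, 1.2, 1.6), read_gap, numeric(1))
  expect_equal(gaps[1], 0, tolerance = 1e-9)
  expect_true(all(diff(gaps) >= 0))
  expect_gt(gaps[5], 0.1)
})

test_that("reading is a pure function of trace and config", {
  p <- trace_params(noise_sd = 0.06, blink_rate = 0.3, seed = 21)
  traces <- purrr::map_dfr(1:5, function(r) {
    q <- p; q$seed <- 21L + r
    simulate_trace(q, repeat_index = r)
  })
  expect_identical(read_session(traces, cfg), read_session(traces, cfg))
})
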