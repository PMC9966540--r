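make_pairs <- function(a, b) {
  tibble::tibble(subject_id = sprintf("S%02d", seq_along(a)), a = a, b = b)
}

test_that("confidence intervals match the closed forms to 1e-12", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(5:80, 1)
    bias <- runif(1, -1, 1)
    s <- runif(1, 0.05, 1)
    res <- loa_confint(bias = bias, n = n, sd = s)
    tq <- qt(0.975, n - 1)
    expect_equal(res$ci_bias_lower, bias - tq * s / sqrt(n),
                 tolerance = 1e-12)
    expect_equal(res$ci_bias_upper, bias + tq * s / sqrt(n),
                 tolerance = 1e-12)
    expect_equal(res$ci_loa_lower_lower,
                 bias - 1.96 * s - tq * s * sqrt(3 / n),
                 tolerance = 1e-12)
    expect_equal(res$ci_loa_upper_upper,
                 bias + 1.96 * s + tq * s * sqrt(3 / n),
                 tolerance = 1e-12)
    expect_equal(res$se_loa, res$se_bias * sqrt(3), tolerance = 1e-12)
    # structural identities of the agreement row
    expect_equal(res$loa_upper - res$loa_lower, 2 * res$coefficient,
                 tolerance = 1e-12)
    expect_equal((res$loa_upper + res$loa_lower) / 2, res$bias,
                 tolerance = 1e-12)
  }
})

test_that("bland_altman reproduces direct computation and degenerate cases", {
  set.seed(11)
  a <- rnorm(30, 4, 0.5)
  b <- a + rnorm(30, 0.1, 0.2)
  res <- bland_altman(make_pairs(a, b), "difference",
                      exclude_outliers = FALSE)
  v <- a - b
  expect_equal(res$bias, mean(v), tolerance = 1e-12)
  expect_equal(res$sd, sd(v), tolerance = 1e-12)
  expect_equal(res$loa_lower, mean(v) - 1.96 * sd(v), tolerance = 1e-12)

  # all differences zero: degenerate zero-width limits
  z <- bland_altman(make_pairs(rep(4, 5), rep(4, 5)), "difference")
  expect_equal(c(z$bias, z$loa_lower, z$loa_upper, z$coefficient),
               rep(0, 4))
  expect_true(z$degenerate)

  expect_error(bland_altman(make_pairs(1:2, 2:3), "difference"),
               "at least 3")
  expect_error(bland_altman(make_pairs(c(1, NA, 3), 1:3), "difference"),
               "complete")
})

test_that("a single injected 5 SD outlier is removed in one pass", {
  set.seed(5)
  a <- rnorm(40, 4, 0.4)
  b <- a - rnorm(40, 0.1, 0.05)
  pairs <- make_pairs(a, b)
  base <- bland_altman(pairs, "difference", exclude_outliers = FALSE)
  pairs$b[17] <- pairs$a[17] - (base$bias + 5 * base$sd)
  res <- bland_altman(pairs, "difference", exclude_outliers = TRUE)
  expect_identical(res$pass, c("all", "outliers_excluded"))
  expect_identical(res$outliers[[1]], "S17")
  expect_identical(res$n[2], 39L)
  # recomputation on the remainder matches direct arithmetic
  v <- (pairs$a - pairs$b)[-17]
  expect_equal(res$bias[2], mean(v), tolerance = 1e-12)
  expect_equal(res$sd[2], sd(v), tolerance = 1e-12)
})

test_that("swapping measurement sets negates differences and inverts ratios", {
  set.seed(13)
  a <- runif(25, 3, 5)
  b <- runif(25, 3, 5)
  fwd <- bland_altman(make_pairs(a, b), "difference",
                      exclude_outliers = FALSE)
  rev <- bland_altman(make_pairs(b, a), "difference",
                      exclude_outliers = FALSE)
  expect_equal(fwd$bias, -rev$bias, tolerance = 1e-12)
  expect_equal(fwd$loa_lower, -rev$loa_upper, tolerance = 1e-12)
  expect_equal(fwd$loa_upper, -rev$loa_lower, tolerance = 1e-12)
  # per-subject ratio inversion
  expect_equal(a / b, 1 / (b / a), tolerance = 1e-12)
})

test_that("proportional bias test matches cor.test and catches construction", {
  # v = average exactly -> r = 1; v = -average -> r = -1
  avg <- seq(3, 5, length.out = 10)
  pairs_up <- make_pairs(avg + avg / 2, avg - avg / 2)    # a - b = avg
  res <- proportional_bias(pairs_up, "difference")
  expect_equal(res$r, 1, tolerance = 1e-9)
  pairs_dn <- make_pairs(avg - avg / 2, avg + avg / 2)
  expect_equal(proportional_bias(pairs_dn, "difference")$r, -1,
               tolerance = 1e-9)

  # independent values and averages: |r| small under the null
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    base <- rnorm(1000, 4, 0.5)
    noise <- rnorm(1000, 0, 0.1)
    pr <- make_pairs(base + noise / 2, base - noise / 2)
    if (abs(proportional_bias(pr, "difference")$r) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 48)

  # degenerate input flagged
  flat <- make_pairs(rep(4, 5), rep(4, 5))
  expect_true(proportional_bias(flat, "difference")$degenerate)
})

test_that("ratio fallback triggers on multiplicative bias and resolves it", {
  # proportional method bias: noise growing with size
  set.seed(101)
  truth <- rnorm(43, 4.12, 0.7)
  a <- 1.023 * truth + rnorm(43, 0, 0.02)
  b <- truth + rnorm(43, 0, 0.02)
  rep_mult <- analyze_pair(make_pairs(a, b))
  expect_true(rep_mult$triggered)
  expect_identical(rep_mult$headline, "ratio")
  last <- rep_mult$ratio[nrow(rep_mult$ratio), ]
  expect_lt(abs(last$bias - 1.023), 0.01)
  # ratio scale removes the proportionality
  expect_gt(last$pearson_p, 0.05)

  # constant offset: no proportional bias, no ratio analysis
  set.seed(102)
  truth <- rnorm(43, 4.12, 0.7)
  rep_add <- analyze_pair(make_pairs(truth + 0.1 + rnorm(43, 0, 0.02),
                                     truth + rnorm(43, 0, 0.02)))
  expect_false(rep_add$triggered)
  expect_null(rep_add$ratio)

  # identical measurements: degenerate, treated as non-significant
  rep_same <- analyze_pair(make_pairs(truth, truth))
  expect_false(rep_same$triggered)
  expect_identical(rep_same$headline, "difference")
})

test_that("ratio trigger has high power at the study's size and bias", {
  triggers <- 0
  for (s in 1:200) {
    pm <- simulate_paired_readings(43, mean = 4.12, sd = 0.70,
                                   ratio_bias = 1.023, noise_sd = 0.02,
                                   seed = s)
    if (analyze_pair(pm)$triggered) triggers <- triggers + 1
  }
  expect_gt(triggers / 200, 0.9)
})

test_that("Q-Q data standardize correctly and flag degenerate input", {
  qq <- qq_data(c(-1, 0, 1))
  expect_equal(qq$theoretical, qnorm(c(1, 3, 5) / 6))
  expect_equal(qq$sample, c(-1, 0, 1))
  expect_equal(qq$sample, -rev(qq$sample))

  # near-unit slope for normal samples
  slopes <- vapply(1:40, function(s) {
    set.seed(s)
    qq <- qq_data(rnorm(500))
    unname(coef(lm(sample ~ theoretical, data = qq))[2])
  }, numeric(1))
  expect_gte(mean(slopes > 0.9 & slopes < 1.1), 0.9)

  const <- qq_data(rep(2, 10))
  expect_true(attr(const, "degenerate"))
  expect_error(qq_data(c(1, 2)), "at least 3")
})

test_that("log-ratio identity holds across random positive pairs", {
  pm <- make_pairs(4.2, 4.1)
  expect_true(log_ratio_equivalence_check(pm))
  set.seed(8)
  big <- make_pairs(runif(10000, 0.1, 10), runif(10000, 0.1, 10))
  expect_true(log_ratio_equivalence_check(big))
  one <- make_pairs(1, 1)
  expect_true(log_ratio_equivalence_check(one))
  expect_error(log_ratio_equivalence_check(make_pairs(-1, 2)), "positive")
})
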