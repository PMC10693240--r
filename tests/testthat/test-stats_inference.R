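test_that("two-group count coefficient equals the log mean ratio", {
  dat <- tibble::tibble(
    latency_s = c(4, 4, 4, 4, 8, 8, 8, 8),
    phase = rep(c("engagement", "agitation"), each = 4),
    day = "playback", is_counter_call = FALSE
  )
  fit <- fit_latency_model(dat, "phase_day", reference = "engagement")
  expect_equal(fit$terms$estimate[fit$terms$term == "agitation"],
               log(2), tolerance = 1e-6)

  # identical groups: zero coefficient
  same <- tibble::tibble(
    latency_s = rep(5, 6),
    phase = rep(c("engagement", "agitation"), each = 3),
    day = "playback", is_counter_call = FALSE
  )
  fit0 <- fit_latency_model(same, "phase_day", reference = "engagement")
  expect_equal(fit0$terms$estimate[fit0$terms$term == "agitation"], 0,
               tolerance = 1e-8)

  # closed-form property on random two-group data, any dispersion
  set.seed(21)
  for (rep in 1:10) {
    y <- c(rnbinom(20, mu = 8, size = 1.5), rnbinom(20, mu = 20, size = 1.5)) + 1
    d <- tibble::tibble(latency_s = y,
                        phase = rep(c("engagement", "agitation"), each = 20),
                        day = "playback", is_counter_call = FALSE)
    f <- fit_latency_model(d, "phase_day", reference = "engagement")
    expect_equal(f$terms$estimate[f$terms$term == "agitation"],
                 log(mean(y[21:40]) / mean(y[1:20])), tolerance = 1e-6)
  }
})

test_that("counter-call predictor contrasts counter vs non-counter latencies", {
  dat <- tibble::tibble(
    latency_s = c(rep(10, 5), rep(30, 5)),
    phase = "engagement", day = "playback",
    is_counter_call = rep(c(TRUE, FALSE), each = 5)
  )
  fit <- fit_latency_model(dat, "counter_call")
  expect_equal(fit$reference_level, "non_counter")
  expect_equal(fit$terms$estimate[fit$terms$term == "counter"],
               log(10 / 30), tolerance = 1e-6)
})

test_that("levels with fewer than two observations are inestimable", {
  dat <- tibble::tibble(
    latency_s = c(4, 5, 6, 8, 9, 10, 99),
    phase = c(rep("engagement", 3), rep("agitation", 3), "disengagement"),
    day = "playback", is_counter_call = FALSE
  )
  fit <- fit_latency_model(dat, "phase_day", reference = "engagement")
  expect_equal(fit$inestimable, "disengagement")
  expect_false("disengagement" %in% fit$terms$term)
  expect_equal(fit$n_obs, 6)
})

test_that("logistic coefficient equals the 2x2 table log odds ratio", {
  # 8/10 vs 2/10 matched: OR = (8*8)/(2*2) = 16
  pairs <- tibble::tibble(
    kind = "E_T", anchor_event = sprintf("p%d", 1:20),
    phase = rep(c("engagement", "agitation"), each = 10),
    first_latency_s = 1, second_latency_s = 1,
    share_small = 45, discrepancy_pp = 10,
    matched = c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  )
  fit <- fit_match_model(pairs, reference = "agitation")
  b <- fit$terms$estimate[fit$terms$term == "engagement"]
  expect_equal(b, log(16), tolerance = 1e-6)
  expect_equal(exp(b), 16, tolerance = 1e-5)

  # equal proportions: OR = 1
  pairs$matched <- rep(c(TRUE, FALSE), 10)
  fit1 <- fit_match_model(pairs, reference = "agitation")
  expect_equal(fit1$terms$estimate[fit1$terms$term == "engagement"], 0,
               tolerance = 1e-8)
})

test_that("complete separation falls back to Haldane-Anscombe odds ratios", {
  pairs <- tibble::tibble(
    kind = "E_T", anchor_event = sprintf("p%d", 1:20),
    phase = rep(c("engagement", "agitation"), each = 10),
    first_latency_s = 1, second_latency_s = 1,
    share_small = 45, discrepancy_pp = 10,
    matched = c(rep(TRUE, 10), rep(TRUE, 2), rep(FALSE, 8))
  )
  fit <- fit_match_model(pairs, reference = "agitation")
  expect_true(fit$separation)
  expected <- log((10.5 / 0.5) / (2.5 / 8.5))
  expect_equal(fit$terms$estimate[fit$terms$term == "engagement"],
               expected, tolerance = 1e-8)
})

test_that("amplitude trend recovers exact linear and constant data", {
  calls <- make_calls(
    onsets = seq(0, 540, by = 60), offsets = seq(1, 541, by = 60),
    sources = rep("subject", 10),
    amplitudes = -20 - seq(0, 9)  # exactly -1 dB per minute
  )
  fit <- suppressWarnings(fit_amplitude_trend(calls, "time_min"))
  expect_equal(fit$terms$estimate, -1, tolerance = 1e-8)
  expect_equal(fit$dispersion, 0, tolerance = 1e-12)

  calls$amplitude_db <- rep(-25, 10)
  flat <- suppressWarnings(fit_amplitude_trend(calls, "time_min"))
  expect_equal(flat$terms$estimate, 0, tolerance = 1e-10)

  calls$amplitude_db <- NA_real_
  expect_error(fit_amplitude_trend(calls, "time_min"),
               class = "antiphony_error_validation")
})

test_that("amplitude phase effects are recovered from group structure", {
  calls <- make_calls(
    onsets = c(1:4, 101:104), offsets = c(1:4, 101:104) + 0.5,
    sources = rep("subject", 8),
    amplitudes = c(rep(-25, 4), rep(-31, 4))
  )
  calls$phase <- rep(c("engagement", "disengagement"), each = 4)
  fit <- suppressWarnings(fit_amplitude_trend(calls, "phase"))
  expect_equal(fit$terms$estimate[fit$terms$term == "disengagement"], -6,
               tolerance = 1e-8)
})

test_that("randomization test is deterministic, bounded and monotone", {
  set.seed(5)
  dat <- tibble::tibble(
    y = c(rpois(15, 6), rpois(15, 14)),
    g = rep(c("a", "b"), each = 15)
  )
  r1 <- randomization_test(dat, "y", "g", family = "nb", coefficient = "b",
                           n_permutations = 300, seed = 42)
  r2 <- randomization_test(dat, "y", "g", family = "nb", coefficient = "b",
                           n_permutations = 300, seed = 42)
  expect_identical(r1$null_betas, r2$null_betas)   # bit-identical given seed
  expect_equal(r1$beta_observed, log(mean(dat$y[16:30]) / mean(dat$y[1:15])))
  expect_gte(r1$p_empirical, 1 / 301)
  expect_lte(r1$p_empirical, 1)
  # p is the add-one two-sided tail of the null
  expect_equal(r1$p_empirical,
               (1 + sum(abs(r1$null_betas) >= abs(r1$beta_observed))) /
                 (r1$n_permutations + 1))

  # constant outcome: beta 0 everywhere, p exactly 1
  const <- tibble::tibble(y = rep(4, 20), g = rep(c("a", "b"), 10))
  r0 <- randomization_test(const, "y", "g", family = "nb",
                           n_permutations = 100, seed = 1)
  expect_equal(r0$beta_observed, 0)
  expect_true(all(r0$null_betas == 0))
  expect_equal(r0$p_empirical, 1)

  # with the null distribution fixed, p is non-increasing in |beta_obs|
  nulls <- r1$null_betas
  p_at <- function(b) (1 + sum(abs(nulls) >= abs(b))) / (length(nulls) + 1)
  bs <- seq(0, 2, by = 0.1)
  expect_true(all(diff(sapply(bs, p_at)) <= 0))
})

test_that("tidy and glance return broom-shaped summaries", {
  dat <- tibble::tibble(
    latency_s = c(4, 5, 6, 9, 10, 11),
    phase = rep(c("engagement", "agitation"), each = 3),
    day = "playback", is_counter_call = FALSE
  )
  fit <- fit_latency_model(dat, "phase_day", reference = "engagement")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(tidy(fit, exponentiate = TRUE)$estimate, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 6)
  expect_equal(gl$family, "neg_binomial")
})
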