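test_that("configs validate probabilities, bounds and blow schedules", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(phase_bounds_s = c(0, 400, 900, 1300)),
               class = "antiphony_error_validation")   # beyond duration
  expect_error(sim_config(phase_bounds_s = c(0, 900, 400, 1200)),
               class = "antiphony_error_validation")
  expect_error(sim_config(response_probability = c(1, 2, 1)),
               class = "antiphony_error_validation")
  expect_error(sim_config(latency_mean_s = c(8, -1, 25)),
               class = "antiphony_error_validation")
})

test_that("a fixed seed reproduces the session and ground truth bit for bit", {
  a <- simulate_playback_session(sim_config(seed = 99))
  b <- simulate_playback_session(sim_config(seed = 99))
  expect_identical(a$session$calls, b$session$calls)
  expect_identical(a$truth, b$truth)
  c <- simulate_playback_session(sim_config(seed = 100))
  expect_false(identical(a$session$calls, c$session$calls))
})

test_that("generated sessions pass event validation and phase structure", {
  for (seed in c(1, 17, 23)) {
    sim <- simulate_playback_session(sim_config(seed = seed))
    s <- sim$session
    expect_s3_class(s, "playback_session")
    expect_true(all(diff(s$calls$onset_s) > 0))
    expect_true(all(s$calls$offset_s >= s$calls$onset_s))
    subj <- s$calls[s$calls$source == "subject", ]
    expect_true(all(is.finite(subj$amplitude_db)))
    # ground truth covers every subject call
    expect_setequal(sim$truth$event_id, subj$event_id)
  }
})

test_that("a silent subject leaves an exemplar-only session", {
  cfg <- sim_config(seed = 2, response_probability = 0,
                    n_final_solo_calls = 0)
  sim <- simulate_playback_session(cfg)
  expect_true(all(sim$session$calls$source == "exemplar"))
  expect_equal(nrow(latency_dataset(sim$session)), 0)
})

test_that("the perfect oscillator limit yields exact 50:50 pairs", {
  sim <- simulate_playback_session(scenario_config("perfect_oscillator", seed = 5))
  et <- extract_response_pairs(sim$session, "E_T")
  te <- extract_response_pairs(sim$session, "T_E")
  expect_gt(nrow(et), 10)
  expect_true(all(abs(et$share_small - 50) < 1e-9))
  expect_true(all(et$matched))
  expect_true(all(abs(te$discrepancy_pp) < 1e-9))
})

test_that("control sessions carry the requested sparse call sequence", {
  cfg <- sim_config(seed = 8)
  ctrl <- simulate_control_session(cfg)
  expect_equal(ctrl$day, "control")
  expect_equal(nrow(ctrl$calls), 6)
  expect_true(all(ctrl$calls$source == "subject"))
  expect_equal(nrow(latency_dataset(ctrl)), 5)
  expect_true(all(latency_dataset(ctrl)$phase == "control"))

  # zero latency noise -> identical control gaps
  flat <- simulate_control_session(sim_config(seed = 8, control_latency_sd_s = 0,
                                              call_duration_sd_s = 0))
  expect_equal(length(unique(round(latency_dataset(flat)$latency_s, 6))), 1)
})

test_that("solo tail calls are non-counter and follow the broadcast stop", {
  sim <- simulate_playback_session(sim_config(seed = 31))
  solo_ids <- sim$truth$event_id[sim$truth$solo]
  expect_equal(length(solo_ids), 3)
  ld <- latency_dataset(sim$session)
  expect_true(all(!ld$is_counter_call[ld$to_event %in% solo_ids]))
  last_ex <- max(sim$session$calls$offset_s[sim$session$calls$source == "exemplar"])
  solo_on <- sim$session$calls$onset_s[sim$session$calls$event_id %in% solo_ids]
  expect_true(all(solo_on > last_ex))
})

test_that("scenario presets cover the paper-like, null and oscillator regimes", {
  lib <- scenario_library(seed = 3)
  expect_setequal(names(lib), c("paper_like", "null", "perfect_oscillator"))
  expect_equal(lib$null$coupling_prob, rep(0, 3))
  expect_equal(length(unique(lib$null$latency_mean_s)), 1)
  expect_equal(nrow(lib$null$blows), 0)
  expect_equal(lib$perfect_oscillator$coupling_prob, rep(1, 3))
  expect_error(scenario_config("bogus"), class = "antiphony_error_validation")
})

test_that("configs round-trip through YAML", {
  cfg <- sim_config(seed = 12, latency_mean_s = c(7, 13, 22))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$latency_mean_s, cfg$latency_mean_s)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$blows$time_s, cfg$blows$time_s)
  # identical seeds simulate identical sessions after the round trip
  expect_identical(simulate_playback_session(back)$session$calls,
                   simulate_playback_session(cfg)$session$calls)
})

test_that("uncoupled pair match rate approaches the numeric chance rate", {
  # uncoupled regime: first latency is N(mu_op, sd) + exemplar duration gap,
  # second is Gamma; the chance of landing in the 41:59 band is computed by
  # Monte Carlo directly from the generating distributions as the oracle
  cfg <- sim_config(
    seed = 44, session_duration_s = 6000,
    phase_bounds_s = c(0, 5900, 5950, 6000),
    response_probability = 1, coupling_prob = 0,
    latency_mean_s = 10, latency_shape = 3,
    broadcast_latency_policy = "fixed_mean", operator_latency_mean_s = 10,
    operator_noise_sd = 1, rebroadcast_wait_s = 60,
    blows = tibble::tibble(time_s = numeric(), kind = character()),
    n_final_solo_calls = 0, broadcast_stop_s = 6000
  )
  sim <- simulate_playback_session(cfg)
  et <- extract_response_pairs(sim$session, "E_T")
  expect_gt(nrow(et), 150)
  emp <- mean(et$matched)

  set.seed(1)
  n <- 200000
  first <- pmax(pmin(rnorm(n, 10, 1), 60), 0.5)
  second <- pmax(rgamma(n, shape = 3, scale = 10 / 3), 0.05)
  share <- 100 * pmin(first, second) / (first + second)
  chance <- mean(share >= 41 - 1e-9)
  se <- sqrt(emp * (1 - emp) / nrow(et))
  expect_lt(abs(emp - chance), 2 * se + 0.02)
})
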