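# Coupled-oscillator session simulator.
#
# Emulates a ~20-min interactive playback exchange: an operator broadcasts an
# exemplar, the subject answers with a phase-dependent probability and
# latency, and the operator times the next broadcast off the subject's
# behavior. Response latencies are either *coupled* — a probabilistic mimicry
# of the latency into the exemplar being answered, operationalizing the
# coupled-oscillator reading of turn-taking with one recoverable parameter
# per phase — or drawn fresh from a right-skewed Gamma with a per-phase mean.
# Scheduled surface blows delay the next response and strip its counter-call
# status. Amplitudes carry an additive per-phase effect so that
# disengagement shows a recoverable decline. Every draw is recorded in a
# ground-truth table for parameter-recovery tests.

# seven blows: two neutral interspersed with the initial broadcasts, three
# wheezy during agitation, two neutral during disengagement
default_blows <- function() {
  tibble(
    time_s = c(10, 25, 480, 600, 760, 950, 1100),
    kind = c("blow_neutral", "blow_neutral", "blow_wheezy", "blow_wheezy",
             "blow_wheezy", "blow_neutral", "blow_neutral")
  )
}

#' Build a simulator configuration
#'
#' Full parameterization of the synthetic playback session generator,
#' validated. Per-phase arguments are length-3 vectors (engagement,
#' agitation, disengagement); scalars are recycled. Defaults describe a
#' 20-min session in which engagement has the shortest response latencies and
#' the strongest latency coupling, agitation is intermediate with wheezy
#' blows, and disengagement has long latencies and declining amplitude; the
#' control day is a short sparse sequence of six calls with much longer
#' inter-call intervals.
#'
#' @param seed Integer seed driving every draw.
#' @param session_duration_s Session length; default 1200 (20 min).
#' @param n_initial_broadcasts Broadcasts before the subject's first
#'   response; default 3.
#' @param phase_bounds_s Increasing boundaries of the three phases,
#'   `c(start, b1, b2, end)`; default `c(0, 420, 900, 1200)`.
#' @param response_probability Per-phase probability that a broadcast is
#'   answered.
#' @param latency_mean_s,latency_shape Per-phase Gamma mean (s) and shape of
#'   uncoupled response latencies.
#' @param coupling_prob Per-phase probability that a response latency mimics
#'   the latency into the exemplar instead of a fresh Gamma draw.
#' @param coupling_noise_sd SD of the multiplicative mimicry noise
#'   (`latency * (1 + eps)`).
#' @param broadcast_latency_policy `"mirror_subject"` (operator copies the
#'   subject's last response latency, plus Gaussian noise) or `"fixed_mean"`.
#' @param operator_latency_mean_s Mean operator latency for `"fixed_mean"`
#'   and for the initial broadcast spacing.
#' @param operator_noise_sd SD of operator latency noise (s).
#' @param rebroadcast_wait_s Wait before re-broadcasting after an unanswered
#'   exemplar.
#' @param blows Schedule tibble (`time_s`, `kind`) of surface blows; a
#'   deterministic schedule, since blows are landmark events that define
#'   phases. `NULL` for the default seven.
#' @param blow_recovery_s A blow falling in the response window pushes the
#'   response to `blow time + blow_recovery_s` (breathing at the surface
#'   disrupts calling); default 30.
#' @param blow_lookahead_s A subject about to surface holds its response: a
#'   blow scheduled within `blow_lookahead_s` after the exemplar interrupts
#'   the response even if the drawn latency would have beaten it; default 15.
#' @param amplitude_base_db Baseline call amplitude (relative dB).
#' @param amplitude_phase_effect_db Per-phase additive amplitude effect (dB).
#' @param amplitude_noise_sd_db Amplitude noise SD (dB).
#' @param broadcast_stop_s Time at which the operator ceases broadcasting;
#'   default 60 s into disengagement (`phase_bounds_s[3] + 60`), mirroring a
#'   trial wound down early once the subject disengages. `NULL` for the
#'   default.
#' @param n_final_solo_calls Number of solo subject calls appended after the
#'   operator stops broadcasting (calls in succession, hence non-counter),
#'   with gaps at the subject's established calling rate; default 3.
#' @param control_n_calls,control_latency_mean_s,control_latency_sd_s
#'   Control-day sequence: number of calls and the Normal (truncated at 0)
#'   inter-call latency distribution.
#' @param call_duration_mean_s,call_duration_sd_s Call duration draw.
#' @param start_delay_s Onset of the first broadcast; default 5.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       session_duration_s = 1200,
                       n_initial_broadcasts = 3,
                       phase_bounds_s = c(0, 420, 900, 1200),
                       response_probability = c(1, 0.9, 0.9),
                       latency_mean_s = c(8, 14, 25),
                       latency_shape = c(2, 2, 2),
                       coupling_prob = c(0.8, 0.3, 0.1),
                       coupling_noise_sd = 0.1,
                       broadcast_latency_policy = c("mirror_subject", "fixed_mean"),
                       operator_latency_mean_s = 8,
                       operator_noise_sd = 1,
                       rebroadcast_wait_s = 20,
                       blows = NULL,
                       blow_recovery_s = 30,
                       blow_lookahead_s = 15,
                       amplitude_base_db = -27,
                       amplitude_phase_effect_db = c(0, -2, -6),
                       amplitude_noise_sd_db = 3,
                       broadcast_stop_s = NULL,
                       n_final_solo_calls = 3,
                       control_n_calls = 6,
                       control_latency_mean_s = 60,
                       control_latency_sd_s = 15,
                       call_duration_mean_s = 1.4,
                       call_duration_sd_s = 0.2,
                       start_delay_s = 5) {
  broadcast_latency_policy <- match.arg(broadcast_latency_policy)
  if (is.null(blows)) blows <- default_blows()
  blows <- as_tibble(blows)
  rec3 <- function(x) if (length(x) == 1) rep(x, 3) else x
  cfg <- list(
    seed = as.integer(seed),
    session_duration_s = session_duration_s,
    n_initial_broadcasts = as.integer(n_initial_broadcasts),
    phase_bounds_s = phase_bounds_s,
    response_probability = rec3(response_probability),
    latency_mean_s = rec3(latency_mean_s),
    latency_shape = rec3(latency_shape),
    coupling_prob = rec3(coupling_prob),
    coupling_noise_sd = coupling_noise_sd,
    broadcast_latency_policy = broadcast_latency_policy,
    operator_latency_mean_s = operator_latency_mean_s,
    operator_noise_sd = operator_noise_sd,
    rebroadcast_wait_s = rebroadcast_wait_s,
    blows = blows,
    blow_recovery_s = blow_recovery_s,
    blow_lookahead_s = blow_lookahead_s,
    amplitude_base_db = amplitude_base_db,
    amplitude_phase_effect_db = rec3(amplitude_phase_effect_db),
    amplitude_noise_sd_db = amplitude_noise_sd_db,
    broadcast_stop_s = if (is.null(broadcast_stop_s)) phase_bounds_s[3] + 60
                       else broadcast_stop_s,
    n_final_solo_calls = as.integer(n_final_solo_calls),
    control_n_calls = as.integer(control_n_calls),
    control_latency_mean_s = control_latency_mean_s,
    control_latency_sd_s = control_latency_sd_s,
    call_duration_mean_s = call_duration_mean_s,
    call_duration_sd_s = call_duration_sd_s,
    start_delay_s = start_delay_s
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  b <- cfg$phase_bounds_s
  if (length(b) != 4 || any(diff(b) <= 0)) {
    abort_validation("phase_bounds_s must be 4 increasing boundaries")
  }
  if (b[4] > cfg$session_duration_s) {
    abort_validation("phase bounds extend beyond the session duration")
  }
  probs <- c(cfg$response_probability, cfg$coupling_prob)
  if (any(probs < 0 | probs > 1)) {
    abort_validation("probabilities must lie in [0, 1]")
  }
  if (any(cfg$latency_mean_s <= 0) || any(cfg$latency_shape <= 0)) {
    abort_validation("latency means and shapes must be positive")
  }
  if (cfg$coupling_noise_sd < 0 || cfg$operator_noise_sd < 0 ||
      cfg$amplitude_noise_sd_db < 0 || cfg$control_latency_sd_s < 0) {
    abort_validation("noise SDs must be nonnegative")
  }
  if (nrow(cfg$blows) > 0) validate_behaviors(tibble(time_s = cfg$blows$time_s,
                                                     kind = cfg$blows$kind,
                                                     note = NA_character_))
  invisible(cfg)
}

config_phases <- function(cfg) {
  b <- cfg$phase_bounds_s
  tibble(label = phase_labels, start_s = b[1:3], end_s = b[2:4])
}

phase_index <- function(t, cfg) {
  b <- cfg$phase_bounds_s
  i <- findInterval(t, b, left.open = FALSE)
  pmin(pmax(i, 1L), 3L)
}

rdur <- function(cfg) max(0.3, rnorm(1, cfg$call_duration_mean_s, cfg$call_duration_sd_s))

#' Simulate an interactive playback session
#'
#' Generates the alternating exemplar/subject timeline described in
#' [sim_config()], with full ground truth. The first `n_initial_broadcasts`
#' exemplars are spaced at the operator mean and draw no response; from then
#' on each broadcast is answered with the current phase's response
#' probability. An answer latency is either coupled — the latency into the
#' answered exemplar times `(1 + eps)` — or a fresh Gamma draw; a scheduled
#' blow inside the gap delays the response to `blow + blow_recovery_s`.
#' Unanswered exemplars are re-broadcast after `rebroadcast_wait_s`.
#'
#' @param config A `sim_config`.
#' @return A `playback_simulation`: list with `session` (a
#'   `playback_session`), `truth` (one row per subject call: coupling
#'   indicator, drawn and realized latencies, blow interruption, phase,
#'   expected amplitude) and `config`.
#' @export
simulate_playback_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  dur <- cfg$session_duration_s
  blow_times <- cfg$blows$time_s

  ev <- list(); tr <- list()
  n_e <- 0L; n_s <- 0L
  t_next <- cfg$start_delay_s
  prev_offset <- NA_real_      # offset of the latest call of either source
  last_subject_offset <- NA_real_
  last_resp_latency <- NA_real_
  n_broadcast <- 0L
  dur_broadcast <- min(dur, cfg$broadcast_stop_s)

  while (t_next < dur_broadcast) {
    # --- broadcast an exemplar
    n_broadcast <- n_broadcast + 1L
    n_e <- n_e + 1L
    e_on <- t_next
    e_off <- e_on + rdur(cfg)
    gap_into_e <- if (is.na(prev_offset)) NA_real_ else e_on - prev_offset
    ev[[length(ev) + 1]] <- tibble(
      event_id = sprintf("E%02d", n_e), source = "exemplar",
      onset_s = e_on, offset_s = e_off, amplitude_db = NA_real_
    )
    prev_offset <- e_off
    if (e_off >= dur) break

    ph <- phase_index(e_off, cfg)
    respond <- n_broadcast >= cfg$n_initial_broadcasts &&
      runif(1) < cfg$response_probability[ph]

    if (respond) {
      coupled <- runif(1) < cfg$coupling_prob[ph] && is.finite(gap_into_e) &&
        gap_into_e > 0
      drawn <- if (coupled) {
        gap_into_e * (1 + rnorm(1, 0, cfg$coupling_noise_sd))
      } else {
        coupled <- FALSE
        rgamma(1, shape = cfg$latency_shape[ph],
               scale = cfg$latency_mean_s[ph] / cfg$latency_shape[ph])
      }
      drawn <- max(drawn, 0.05)
      t_on <- e_off + drawn
      inb <- blow_times > e_off &
        blow_times < max(t_on, e_off + cfg$blow_lookahead_s)
      interrupted <- any(inb)
      if (interrupted) t_on <- max(t_on, max(blow_times[inb]) + cfg$blow_recovery_s)
      if (t_on >= dur) break
      realized <- t_on - e_off
      t_off <- t_on + rdur(cfg)
      ph_t <- phase_index(t_on, cfg)
      amp_mean <- cfg$amplitude_base_db + cfg$amplitude_phase_effect_db[ph_t]
      amp <- amp_mean + rnorm(1, 0, cfg$amplitude_noise_sd_db)
      n_s <- n_s + 1L
      ev[[length(ev) + 1]] <- tibble(
        event_id = sprintf("T%02d", n_s), source = "subject",
        onset_s = t_on, offset_s = t_off, amplitude_db = amp
      )
      tr[[length(tr) + 1]] <- tibble(
        event_id = sprintf("T%02d", n_s),
        exemplar_id = sprintf("E%02d", n_e),
        phase = phase_labels[ph_t],
        draw_phase = phase_labels[ph],
        coupled = coupled,
        solo = FALSE,
        drawn_latency_s = drawn,
        realized_latency_s = realized,
        blow_interrupted = interrupted,
        latency_mean_truth_s = cfg$latency_mean_s[ph_t],
        amplitude_mean_truth_db = amp_mean
      )
      prev_offset <- t_off
      last_subject_offset <- t_off
      last_resp_latency <- realized
      op_lat <- if (cfg$broadcast_latency_policy == "mirror_subject") {
        last_resp_latency + rnorm(1, 0, cfg$operator_noise_sd)
      } else {
        rnorm(1, cfg$operator_latency_mean_s, cfg$operator_noise_sd)
      }
      # the operator never out-waits the rebroadcast timeout
      op_lat <- min(max(op_lat, 0.5), cfg$rebroadcast_wait_s)
      t_next <- t_off + op_lat
    } else if (n_broadcast < cfg$n_initial_broadcasts) {
      t_next <- e_off + max(rnorm(1, cfg$operator_latency_mean_s,
                                  cfg$operator_noise_sd), 0.5)
    } else {
      t_next <- e_off + cfg$rebroadcast_wait_s
    }
  }

  # solo tail: calls in succession after broadcasting has ceased
  if (cfg$n_final_solo_calls > 0 && is.finite(last_subject_offset)) {
    t_prev_off <- last_subject_offset
    for (k in seq_len(cfg$n_final_solo_calls)) {
      ph <- phase_index(t_prev_off, cfg)
      # the subject keeps calling at her current rate: a solo inter-call gap
      # spans what operator latency + exemplar + response latency did, pinned
      # to her last realized response latency (or the phase mean if none)
      base_resp <- if (is.finite(last_resp_latency)) last_resp_latency
                   else cfg$latency_mean_s[ph]
      solo_gap_mean <- 2 * base_resp + cfg$call_duration_mean_s
      drawn <- rgamma(1, shape = cfg$latency_shape[ph],
                      scale = solo_gap_mean / cfg$latency_shape[ph])
      t_on <- t_prev_off + max(drawn, 0.05)
      t_off <- t_on + rdur(cfg)
      ph_t <- phase_index(t_on, cfg)
      amp_mean <- cfg$amplitude_base_db + cfg$amplitude_phase_effect_db[ph_t]
      n_s <- n_s + 1L
      ev[[length(ev) + 1]] <- tibble(
        event_id = sprintf("T%02d", n_s), source = "subject",
        onset_s = t_on, offset_s = t_off,
        amplitude_db = amp_mean + rnorm(1, 0, cfg$amplitude_noise_sd_db)
      )
      tr[[length(tr) + 1]] <- tibble(
        event_id = sprintf("T%02d", n_s),
        exemplar_id = NA_character_,
        phase = phase_labels[ph_t],
        draw_phase = phase_labels[ph],
        coupled = FALSE,
        solo = TRUE,
        drawn_latency_s = drawn,
        realized_latency_s = t_on - t_prev_off,
        blow_interrupted = FALSE,
        latency_mean_truth_s = cfg$latency_mean_s[ph_t],
        amplitude_mean_truth_db = amp_mean
      )
      t_prev_off <- t_off
    }
  }

  calls <- dplyr::bind_rows(ev)
  behaviors <- if (nrow(cfg$blows) > 0) {
    tibble(time_s = cfg$blows$time_s, kind = cfg$blows$kind, note = NA_character_)
  } else {
    NULL
  }
  session <- assemble_session(calls, behaviors, config_phases(cfg), day = "playback")
  truth <- if (length(tr) > 0) dplyr::bind_rows(tr) else tibble(
    event_id = character(), exemplar_id = character(), phase = character(),
    draw_phase = character(), coupled = logical(), solo = logical(),
    drawn_latency_s = numeric(),
    realized_latency_s = numeric(), blow_interrupted = logical(),
    latency_mean_truth_s = numeric(), amplitude_mean_truth_db = numeric()
  )
  structure(list(session = session, truth = truth, config = config),
            class = "playback_simulation")
}

#' @export
print.playback_simulation <- function(x, ...) {
  cat("<playback_simulation> seed:", x$config$seed, "\n")
  print(x$session)
  cat("  subject responses:", nrow(x$truth),
      "(", sum(x$truth$coupled), "coupled )\n")
  invisible(x)
}

#' Simulate a control-day session
#'
#' A short, sparse sequence of subject calls passively recorded outside any
#' playback context: `control_n_calls` calls whose inter-call latencies are
#' Normal(`control_latency_mean_s`, `control_latency_sd_s`) truncated at
#' zero. No exemplars, no phase structure (one `control` interval spanning
#' the sequence).
#'
#' @param config A `sim_config`.
#' @return A `playback_session` with `day = "control"`.
#' @export
simulate_control_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  n <- cfg$control_n_calls
  lat <- pmax(rnorm(max(n - 1, 0), cfg$control_latency_mean_s,
                    cfg$control_latency_sd_s), 0.1)
  durs <- vapply(seq_len(n), function(i) rdur(cfg), numeric(1))
  onsets <- numeric(n)
  onsets[1] <- 30
  for (i in seq_len(n - 1)) {
    onsets[i + 1] <- onsets[i] + durs[i] + lat[i]
  }
  calls <- tibble(
    event_id = sprintf("C%02d", seq_len(n)),
    source = "subject",
    onset_s = onsets,
    offset_s = onsets + durs,
    amplitude_db = cfg$amplitude_base_db + rnorm(n, 0, cfg$amplitude_noise_sd_db)
  )
  phases <- tibble(label = "control", start_s = 0,
                   end_s = max(calls$offset_s) + 1)
  assemble_session(calls, NULL, phases, day = "control")
}

#' Named scenario presets
#'
#' Ready-made simulator configurations:
#' * `"paper_like"` — the default [sim_config()]: engagement with short,
#'   strongly coupled latencies; agitation intermediate with wheezy blows;
#'   disengagement with long latencies and a −6 dB amplitude effect.
#' * `"null"` — no structure: identical phases, zero coupling, fixed-mean
#'   operator, no blows; latencies are i.i.d. across phases, the correct
#'   reference condition for type-I-error calibration of permutation tests.
#' * `"perfect_oscillator"` — deterministic mimicry: every response copies
#'   the latency into its exemplar exactly, so every response pair is 50:50.
#'
#' @param seed Seed stored in each config; default 1.
#' @return Named list of `sim_config` objects.
#' @export
scenario_library <- function(seed = 1) {
  list(
    paper_like = sim_config(seed = seed),
    null = sim_config(
      seed = seed,
      response_probability = 0.9,
      latency_mean_s = 12,
      latency_shape = 4,
      coupling_prob = 0,
      broadcast_latency_policy = "fixed_mean",
      blows = tibble(time_s = numeric(), kind = character()),
      amplitude_phase_effect_db = 0,
      broadcast_stop_s = 1200,
      n_final_solo_calls = 0
    ),
    perfect_oscillator = sim_config(
      seed = seed,
      response_probability = 1,
      coupling_prob = 1,
      coupling_noise_sd = 0,
      operator_noise_sd = 0,
      broadcast_latency_policy = "mirror_subject",
      blows = tibble(time_s = numeric(), kind = character()),
      broadcast_stop_s = 1200,
      n_final_solo_calls = 0
    )
  )
}

#' @rdname scenario_library
#' @param name Preset name.
#' @export
scenario_config <- function(name, seed = 1) {
  lib <- scenario_library(seed)
  if (!name %in% names(lib)) {
    abort_validation(paste0("unknown scenario \"", name, "\"; available: ",
                            paste(names(lib), collapse = ", ")))
  }
  lib[[name]]
}

#' Read / write simulator configurations as YAML
#'
#' The YAML file mirrors the [sim_config()] fields; `blows` is a list of
#' `{time_s, kind}` entries.
#'
#' @param path File path.
#' @return `read_sim_config()`: a `sim_config`; `write_sim_config()`:
#'   `path`, invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort_format(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$blows)) {
    raw$blows <- dplyr::bind_rows(lapply(raw$blows, as_tibble))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$blows <- purrr::pmap(config$blows, function(time_s, kind, ...) {
    list(time_s = time_s, kind = kind)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
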