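# In-code fixtures: small hand-built sessions and random session generators.

make_calls <- function(onsets, offsets, sources, amplitudes = NULL,
                       ids = NULL) {
  n <- length(onsets)
  tibble::tibble(
    event_id = if (is.null(ids)) sprintf("ev%02d", seq_len(n)) else ids,
    source = sources,
    onset_s = onsets,
    offset_s = offsets,
    amplitude_db = if (is.null(amplitudes)) rep(NA_real_, n) else amplitudes
  )
}

make_behaviors <- function(times, kinds) {
  tibble::tibble(time_s = times, kind = kinds, note = NA_character_)
}

make_phases <- function(labels, starts, ends) {
  tibble::tibble(label = labels, start_s = starts, end_s = ends)
}

# a random small session: alternating-ish calls with random sources, plus
# random behavior events, for oracle comparisons
random_small_session <- function(n_calls = 8, n_behaviors = 3, t_max = 100) {
  onsets <- sort(runif(n_calls, 0, t_max))
  durs <- runif(n_calls, 0.2, 1.0)
  # keep calls non-overlapping so ordering is unambiguous
  for (i in seq_len(n_calls - 1)) {
    durs[i] <- min(durs[i], (onsets[i + 1] - onsets[i]) * 0.9)
  }
  calls <- make_calls(
    onsets, onsets + durs,
    sample(c("exemplar", "subject"), n_calls, replace = TRUE)
  )
  behaviors <- make_behaviors(
    runif(n_behaviors, 0, t_max),
    sample(c("blow_neutral", "blow_wheezy", "surfacing", "other"),
           n_behaviors, replace = TRUE)
  )
  assemble_session(calls, behaviors, NULL, day = "playback")
}

# independent brute-force counter-call oracle: a linear scan of the merged,
# time-ordered event timeline (calls and behaviors interleaved)
oracle_counter_flags <- function(session) {
  timeline <- rbind(
    data.frame(time = session$calls$onset_s, end = session$calls$offset_s,
               type = session$calls$source, id = session$calls$event_id),
    data.frame(time = session$behaviors$time_s, end = session$behaviors$time_s,
               type = if (nrow(session$behaviors) > 0)
                 paste0("beh_", session$behaviors$kind) else character(),
               id = rep(NA_character_, nrow(session$behaviors)))
  )
  timeline <- timeline[order(timeline$time), ]
  subj <- session$calls[session$calls$source == "subject", ]
  out <- logical(nrow(subj))
  breaking <- paste0("beh_", c("blow_neutral", "blow_wheezy", "surfacing"))
  for (i in seq_len(nrow(subj))) {
    onset <- subj$onset_s[i]
    prior_calls <- timeline[timeline$type %in% c("exemplar", "subject") &
                              timeline$time < onset &
                              timeline$id != subj$event_id[i] |
                              is.na(timeline$id) & FALSE, ]
    prior_calls <- prior_calls[!is.na(prior_calls$id), ]
    if (nrow(prior_calls) == 0) { out[i] <- FALSE; next }
    lastc <- prior_calls[nrow(prior_calls), ]
    if (lastc$type != "exemplar") { out[i] <- FALSE; next }
    blows <- timeline[timeline$type %in% breaking, ]
    out[i] <- !any(blows$time > lastc$end & blows$time < onset)
  }
  stats::setNames(out, subj$event_id)
}
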