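# Inter-call latency extraction and counter-call classification.
#
# Latency is defined as the time difference between the preceding call's
# offset and the subsequent call's onset, within one source. A subject call
# is a counter call when the most recent prior call (of either source) is an
# exemplar and no surfacing/blow falls in the open interval between that
# exemplar's offset and the subject call's onset.

#' Compute inter-call latencies for one source
#'
#' One latency record per consecutive pair of same-source calls, in time
#' order: `latency_s = onset(to) - offset(from)`. The phase of a record is the
#' phase at the *terminating* call's onset (the response is the event being
#' explained). Overlapping same-source calls (negative latency) are excluded
#' with a warning rather than clamped to zero, annotation error being the
#' likelier cause; the number excluded is kept in attribute
#' `n_overlap_excluded`.
#'
#' @param session A `playback_session`.
#' @param source `"subject"` or `"exemplar"`.
#' @return Tibble with columns `from_event`, `to_event`, `latency_s`, `phase`,
#'   `day`, `source`; zero rows if fewer than two calls of the source.
#' @export
compute_latencies <- function(session, source = c("subject", "exemplar")) {
  assert_session(session)
  source <- match.arg(source)
  calls <- dplyr::filter(session$calls, .data$source == !!source)
  empty <- tibble(
    from_event = character(), to_event = character(), latency_s = numeric(),
    phase = character(), day = character(), source = character()
  )
  if (nrow(calls) < 2) {
    attr(empty, "n_overlap_excluded") <- 0L
    return(empty)
  }
  n <- nrow(calls)
  rec <- tibble(
    from_event = calls$event_id[-n],
    to_event = calls$event_id[-1],
    latency_s = calls$onset_s[-1] - calls$offset_s[-n],
    phase = calls$phase[-1],
    day = session$day,
    source = source
  )
  neg <- rec$latency_s < 0
  if (any(neg)) {
    warn(paste0(sum(neg), " overlapping same-source call pair(s) excluded from latencies"),
         class = "antiphony_warning_overlap")
    rec <- rec[!neg, ]
  }
  attr(rec, "n_overlap_excluded") <- sum(neg)
  rec
}

# counter-call status of every subject call, by a single forward scan of the
# merged call timeline plus a behavior lookup
counter_flags <- function(session) {
  calls <- session$calls
  subj <- dplyr::filter(calls, .data$source == "subject")
  if (nrow(subj) == 0) {
    return(tibble(event_id = character(), is_counter_call = logical()))
  }
  beh <- session$behaviors
  beh_times <- beh$time_s[beh$kind %in% intervening_kinds]
  flag <- logical(nrow(subj))
  for (i in seq_len(nrow(subj))) {
    onset <- subj$onset_s[i]
    prior <- calls[calls$onset_s < onset, ]
    prior <- prior[prior$event_id != subj$event_id[i], ]
    if (nrow(prior) == 0) next
    last_prior <- prior[nrow(prior), ]
    if (last_prior$source != "exemplar") next
    blocked <- any(beh_times > last_prior$offset_s & beh_times < onset)
    flag[i] <- !blocked
  }
  tibble(event_id = subj$event_id, is_counter_call = flag)
}

#' Classify counter calls
#'
#' A subject call is a *counter call* when it directly answers an exemplar:
#' the most recent prior call is an exemplar and no surfacing or respiratory
#' blow occurs in the open interval between that exemplar's offset and the
#' subject call's onset (breathing at the surface disrupts the ease of
#' calling). Subject calls produced in succession (most recent prior call is
#' another subject call) are not counter calls. The flag is attached to the
#' subject-to-subject latency record *terminating* at each call.
#'
#' An intervening exemplar between two subject calls does not remove the
#' latency record from the dataset; it only feeds the most-recent-prior-call
#' rule. With `strict = TRUE`, records that are *neither* clean exchanges nor
#' clean successions — an exemplar intervenes between the two subject calls
#' yet the terminating call is not a counter call (a blow broke the chain) —
#' are dropped instead of kept flagged non-counter.
#'
#' @param session A `playback_session`.
#' @param strict Drop mixed records as described above; default `FALSE`.
#' @return The subject latency records of [compute_latencies()] with an added
#'   logical column `is_counter_call`.
#' @export
classify_counter_calls <- function(session, strict = FALSE) {
  assert_session(session)
  rec <- compute_latencies(session, "subject")
  flags <- counter_flags(session)
  out <- dplyr::left_join(rec, flags, by = c(to_event = "event_id"))
  out$is_counter_call[is.na(out$is_counter_call)] <- FALSE
  if (strict && nrow(out) > 0) {
    calls <- session$calls
    subj <- dplyr::filter(calls, .data$source == "subject")
    onset_of <- setNames(subj$onset_s, subj$event_id)
    offset_of <- setNames(subj$offset_s, subj$event_id)
    ex_on <- calls$onset_s[calls$source == "exemplar"]
    has_ex <- vapply(seq_len(nrow(out)), function(i) {
      any(ex_on > offset_of[out$from_event[i]] &
            ex_on < onset_of[out$to_event[i]])
    }, logical(1))
    out <- out[!(has_ex & !out$is_counter_call), ]
  }
  attr(out, "n_overlap_excluded") <- attr(rec, "n_overlap_excluded")
  out
}

#' Pool latency records across sessions into an analysis table
#'
#' Builds the analysis-ready subject-latency dataset: one row per consecutive
#' pair of subject calls, pooled over the supplied sessions. Control-day
#' records carry `phase = "control"`. Unphased playback records keep phase
#' `"unphased"`; downstream phase-stratified fits drop them while
#' whole-series fits (e.g. the counter-call contrast) retain them.
#'
#' @param sessions A `playback_session` or a list of them.
#' @return Tibble with columns `latency_s`, `phase`, `day`,
#'   `is_counter_call`, `from_event`, `to_event`.
#' @export
latency_dataset <- function(sessions) {
  if (is_playback_session(sessions)) sessions <- list(sessions)
  if (length(sessions) == 0) {
    abort_validation("at least one session is required")
  }
  purrr::map_dfr(sessions, function(s) {
    assert_session(s)
    rec <- classify_counter_calls(s)
    if (s$day == "control") rec$phase <- "control"
    rec[, c("latency_s", "phase", "day", "is_counter_call",
            "from_event", "to_event")]
  })
}
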