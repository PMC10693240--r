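# Response-pair extraction and latency-ratio matching.
#
# A response pair compares the latency *into* a call with the latency *out of*
# it. For an E_T pair anchored on exemplar E: the first latency runs from the
# preceding subject call's offset to E's onset (the operator's response time),
# the second from E's offset to the answering subject call's onset (the
# subject's response time). T_E is the mirror construction anchored on a
# subject call. Both sub-intervals must be free of intervening calls, i.e. the
# three events are consecutive on the merged call timeline.
#
# The two latencies of a pair are standardized to percentage shares of their
# sum; a pair is a "match" when its shares fall between 41:59 and 50:50
# (band edge inclusive).

MATCH_THRESHOLD <- 41
# floating-point tie tolerance on the band edge: a pair like 4.1 s / 5.9 s
# has an exact share of 41 but a computed one a few ulps below it
SHARE_EPS <- 1e-9

#' Standardized latency-ratio metrics for response pairs
#'
#' Standardizes a pair of positive latencies to percentage shares of their
#' sum, so that pairs are comparable across absolute durations. Returns the
#' smaller share (`share_small`, in `[0, 50]`), the discrepancy between the
#' two shares in percentage points (`discrepancy_pp = 100 - 2 * share_small`),
#' and the binary match flag (`matched`, true when `share_small >=
#' match_threshold`, i.e. the ratio lies between 41:59 and 50:50 under the
#' default band). A perfect match is a 50:50 ratio, discrepancy 0.
#'
#' All metrics are symmetric in the two latencies and invariant to scaling
#' both by a common positive factor.
#'
#' @param first_latency_s,second_latency_s Positive latencies in seconds
#'   (vectorized).
#' @param match_threshold Smallest matching share, in percent; default 41.
#' @return Tibble with columns `first_latency_s`, `second_latency_s`,
#'   `share_small`, `discrepancy_pp`, `matched`.
#' @examples
#' pair_metrics(4.1, 5.9)  # band edge: share 41, matched
#' pair_metrics(7, 7)      # perfect 50:50 match
#' pair_metrics(3, 7)      # share 30, discrepancy 40, unmatched
#' @export
pair_metrics <- function(first_latency_s, second_latency_s,
                         match_threshold = MATCH_THRESHOLD) {
  if (any(first_latency_s <= 0) || any(second_latency_s <= 0)) {
    abort_validation("pair latencies must be positive")
  }
  share_small <- 100 * pmin(first_latency_s, second_latency_s) /
    (first_latency_s + second_latency_s)
  tibble(
    first_latency_s = first_latency_s,
    second_latency_s = second_latency_s,
    share_small = share_small,
    discrepancy_pp = 100 - 2 * share_small,
    matched = share_small >= match_threshold - SHARE_EPS
  )
}

#' Extract exemplar-subject response pairs
#'
#' Walks the merged call timeline of a playback session and extracts response
#' pairs of the requested kind. For `"E_T"`, each exemplar whose immediate
#' neighbours on the timeline are a preceding subject call and a following
#' (answering) subject call yields one pair: first latency into the exemplar,
#' second latency out of it. `"T_E"` is the mirror: subject calls flanked by
#' exemplars. Pairs with a non-positive latency are dropped with a warning.
#' The phase of a pair is the phase at the terminating (answering) event's
#' onset.
#'
#' @param session A `playback_session` with `day = "playback"`.
#' @param kind `"E_T"` or `"T_E"`.
#' @param match_threshold Passed to [pair_metrics()].
#' @param strategy Pair construction. `"response_time"` (default) compares
#'   the latency into a call with the latency out of it, as above.
#'   `"same_source_interval"` is an exploratory alternative pairing the i-th
#'   exemplar-source inter-call interval with the i-th subject-source one.
#' @return Tibble with columns `kind`, `anchor_event`, `phase`,
#'   `first_latency_s`, `second_latency_s`, `share_small`, `discrepancy_pp`,
#'   `matched`.
#' @export
extract_response_pairs <- function(session, kind = c("E_T", "T_E"),
                                   match_threshold = MATCH_THRESHOLD,
                                   strategy = c("response_time",
                                                "same_source_interval")) {
  assert_session(session)
  kind <- match.arg(kind)
  strategy <- match.arg(strategy)
  if (session$day == "control") {
    abort_validation("response pairs require a playback session (control sessions have no exemplars)")
  }
  empty <- tibble(
    kind = character(), anchor_event = character(), phase = character(),
    first_latency_s = numeric(), second_latency_s = numeric(),
    share_small = numeric(), discrepancy_pp = numeric(), matched = logical()
  )

  if (strategy == "same_source_interval") {
    le <- compute_latencies(session, "exemplar")
    ls <- compute_latencies(session, "subject")
    k <- min(nrow(le), nrow(ls))
    if (k == 0) return(empty)
    first <- le$latency_s[seq_len(k)]
    second <- ls$latency_s[seq_len(k)]
    keep <- first > 0 & second > 0
    if (any(!keep)) {
      warn(paste0(sum(!keep), " pair(s) with non-positive latency dropped"),
           class = "antiphony_warning_pair")
    }
    if (!any(keep)) return(empty)
    m <- pair_metrics(first[keep], second[keep], match_threshold)
    return(dplyr::bind_cols(
      tibble(kind = kind,
             anchor_event = ls$to_event[seq_len(k)][keep],
             phase = ls$phase[seq_len(k)][keep]),
      m
    ))
  }

  calls <- session$calls
  n <- nrow(calls)
  if (n < 3) return(empty)
  anchor_src <- if (kind == "E_T") "exemplar" else "subject"
  flank_src <- setdiff(call_sources, anchor_src)

  idx <- which(calls$source[2:(n - 1)] == anchor_src) + 1L
  rows <- purrr::map_dfr(idx, function(i) {
    if (calls$source[i - 1] != flank_src || calls$source[i + 1] != flank_src) {
      return(NULL)
    }
    tibble(
      anchor_event = calls$event_id[i],
      phase = calls$phase[i + 1],
      first_latency_s = calls$onset_s[i] - calls$offset_s[i - 1],
      second_latency_s = calls$onset_s[i + 1] - calls$offset_s[i]
    )
  })
  if (nrow(rows) == 0) return(empty)
  keep <- rows$first_latency_s > 0 & rows$second_latency_s > 0
  if (any(!keep)) {
    warn(paste0(sum(!keep), " pair(s) with non-positive latency dropped"),
         class = "antiphony_warning_pair")
  }
  rows <- rows[keep, ]
  if (nrow(rows) == 0) return(empty)
  m <- pair_metrics(rows$first_latency_s, rows$second_latency_s, match_threshold)
  dplyr::bind_cols(
    tibble(kind = kind, anchor_event = rows$anchor_event, phase = rows$phase),
    m[, c("first_latency_s", "second_latency_s", "share_small",
          "discrepancy_pp", "matched")]
  )
}

#' Per-phase match counts
#'
#' Partitions response pairs by phase and counts matches. Phases represented
#' by fewer than `min_pairs` pairs are flagged `insufficient` and should be
#' excluded from inference (a phase with a single pair cannot inform a
#' proportion contrast); phases with zero pairs are absent from the output.
#'
#' @param pairs Tibble from [extract_response_pairs()].
#' @param min_pairs Minimum pairs per phase for inference; default 2.
#' @return Tibble with columns `phase`, `n_pairs`, `n_matched`,
#'   `n_unmatched`, `insufficient`.
#' @export
match_rate_by_phase <- function(pairs, min_pairs = 2) {
  if (nrow(pairs) == 0) {
    abort_validation("`pairs` must contain at least one response pair")
  }
  pairs |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_matched = sum(.data$matched),
      n_unmatched = sum(!.data$matched),
      .groups = "drop"
    ) |>
    dplyr::mutate(insufficient = .data$n_pairs < min_pairs)
}

#' Pair-level discrepancy dataset
#'
#' One row per response pair with the exact discrepancy between the pair's
#' standardized shares (`discrepancy_pp`) and its value rounded to the
#' nearest integer percentage point (`discrepancy_int`) for count-family
#' regression.
#'
#' @param pairs Tibble from [extract_response_pairs()] (one kind or both,
#'   row-bound).
#' @return Tibble with columns `discrepancy_pp`, `discrepancy_int`, `phase`,
#'   `kind`.
#' @export
discrepancy_dataset <- function(pairs) {
  if (nrow(pairs) == 0) {
    abort_validation("`pairs` must contain at least one response pair")
  }
  tibble(
    discrepancy_pp = pairs$discrepancy_pp,
    discrepancy_int = as.integer(round(pairs$discrepancy_pp)),
    phase = pairs$phase,
    kind = pairs$kind
  )
}
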