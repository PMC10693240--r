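# Event-table IO and session assembly.
#
# Two dialects are supported for call tables:
#   * "raven"  — tab-delimited Raven Pro selection table ("Begin Time (s)",
#     "End Time (s)", plus a user-named annotation column giving the source);
#   * "simple" — plain TSV with event_id, source, onset_s, offset_s,
#     amplitude_db.
# Times are seconds from session start, fractional (millisecond resolution or
# better, as Raven exports them).

raven_begin_col <- "Begin Time (s)"
raven_end_col <- "End Time (s)"

read_tsv_chr <- function(path) {
  if (!file.exists(path)) {
    abort_format(paste0("file not found: ", path))
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

# convert a character column to numeric, failing loudly with the 1-based data
# row index of the first offending value
parse_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "")
  if (length(bad) > 0) {
    abort_parse(paste0(
      "non-numeric value ", encodeString(x[bad[1]], quote = "\""),
      " in column \"", col, "\", row ", bad[1], " of ", path
    ), row = bad[1], column = col)
  }
  out
}

canonical_source <- function(x, source_map, path) {
  key <- tolower(trimws(x))
  mapped <- unname(source_map[key])
  bad <- which(is.na(mapped))
  if (length(bad) > 0) {
    abort_parse(paste0(
      "unrecognised source value ", encodeString(x[bad[1]], quote = "\""),
      " in row ", bad[1], " of ", path,
      " (expected one of: ", paste(names(source_map), collapse = ", "), ")"
    ), row = bad[1])
  }
  mapped
}

#' Read a call-event table
#'
#' Reads an annotated acoustic-event table into a tibble of call events, one
#' row per vocalization or broadcast, sorted by onset time. The `"raven"`
#' dialect expects the Raven Pro selection-table layout: tab-delimited with
#' header columns `"Begin Time (s)"` and `"End Time (s)"` plus an annotation
#' column naming the source of each event. The `"simple"` dialect expects
#' columns `event_id`, `source`, `onset_s`, `offset_s`, `amplitude_db`.
#'
#' @param path Path to a tab-delimited selection table.
#' @param dialect `"raven"` or `"simple"`.
#' @param source_col Name of the annotation column holding the event source
#'   (`"raven"` dialect only). Raven custom columns are user-named, so this is
#'   configurable; default `"Source"`.
#' @param amplitude_col Name of the column holding a relative amplitude in dB,
#'   if present (`"raven"` dialect only). Default
#'   `"Peak Power Density (dB)"`.
#' @param source_map Named character vector mapping (lower-cased) raw source
#'   annotations to `"exemplar"` / `"subject"`. The default accepts
#'   `exemplar`/`e` and `subject`/`t`, case-insensitively.
#' @return A tibble with columns `event_id`, `source`, `onset_s`, `offset_s`,
#'   `amplitude_db`, sorted by `onset_s`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c(
#'   "Selection\tBegin Time (s)\tEnd Time (s)\tSource",
#'   "1\t1.0\t1.5\texemplar",
#'   "2\t4.0\t4.6\tsubject"
#' ), f)
#' read_selection_table(f)
#' @export
read_selection_table <- function(path,
                                 dialect = c("raven", "simple"),
                                 source_col = "Source",
                                 amplitude_col = "Peak Power Density (dB)",
                                 source_map = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(source_map)) {
    source_map <- c(exemplar = "exemplar", e = "exemplar",
                    subject = "subject", t = "subject")
  }
  raw <- read_tsv_chr(path)

  if (dialect == "raven") {
    required <- c(raven_begin_col, raven_end_col, source_col)
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0) {
      abort_format(paste0(
        "missing required column ", encodeString(missing[1], quote = "\""),
        " in ", path
      ), column = missing[1])
    }
    amp <- if (amplitude_col %in% names(raw)) {
      parse_numeric_col(raw[[amplitude_col]], amplitude_col, path)
    } else {
      rep(NA_real_, nrow(raw))
    }
    ids <- if ("Selection" %in% names(raw)) raw[["Selection"]] else as.character(seq_len(nrow(raw)))
    calls <- tibble(
      event_id = ids,
      source = canonical_source(raw[[source_col]], source_map, path),
      onset_s = parse_numeric_col(raw[[raven_begin_col]], raven_begin_col, path),
      offset_s = parse_numeric_col(raw[[raven_end_col]], raven_end_col, path),
      amplitude_db = amp
    )
  } else {
    required <- c("event_id", "source", "onset_s", "offset_s")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0) {
      abort_format(paste0(
        "missing required column ", encodeString(missing[1], quote = "\""),
        " in ", path
      ), column = missing[1])
    }
    amp <- if ("amplitude_db" %in% names(raw)) {
      parse_numeric_col(raw[["amplitude_db"]], "amplitude_db", path)
    } else {
      rep(NA_real_, nrow(raw))
    }
    calls <- tibble(
      event_id = raw[["event_id"]],
      source = canonical_source(raw[["source"]], source_map, path),
      onset_s = parse_numeric_col(raw[["onset_s"]], "onset_s", path),
      offset_s = parse_numeric_col(raw[["offset_s"]], "offset_s", path),
      amplitude_db = amp
    )
  }
  calls <- dplyr::arrange(calls, .data$onset_s, .data$offset_s)
  validate_calls(calls)
  calls
}

#' Write a call-event table
#'
#' Inverse of [read_selection_table()]: writes a call tibble as a tab-delimited
#' selection table. Round-tripping preserves event count, sources and times
#' (full double precision is written).
#'
#' @param calls Tibble of call events (`event_id`, `source`, `onset_s`,
#'   `offset_s`, `amplitude_db`).
#' @inheritParams read_selection_table
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(calls, path,
                                  dialect = c("raven", "simple"),
                                  source_col = "Source",
                                  amplitude_col = "Peak Power Density (dB)") {
  dialect <- match.arg(dialect)
  validate_calls(calls)
  if (dialect == "raven") {
    out <- tibble(
      Selection = calls$event_id,
      !!raven_begin_col := calls$onset_s,
      !!raven_end_col := calls$offset_s,
      !!source_col := calls$source,
      !!amplitude_col := calls$amplitude_db
    )
  } else {
    out <- calls[, c("event_id", "source", "onset_s", "offset_s", "amplitude_db")]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

validate_calls <- function(calls) {
  if (nrow(calls) == 0) return(invisible(calls))
  if (any(!calls$source %in% call_sources)) {
    abort_validation("call sources must be 'exemplar' or 'subject'")
  }
  if (any(calls$onset_s < 0)) {
    abort_validation("call onsets must be >= 0 s")
  }
  if (any(calls$offset_s < calls$onset_s)) {
    abort_validation("call offsets must not precede onsets")
  }
  amp <- calls$amplitude_db
  if (any(!is.na(amp) & !is.finite(amp))) {
    abort_validation("amplitude_db must be finite where present")
  }
  invisible(calls)
}

#' Read a behavior-event table
#'
#' TSV with columns `time_s`, `kind` (`blow_neutral`, `blow_wheezy`,
#' `surfacing`, `other`) and optional `note`. Behavior events (surfacings and
#' respiratory blows) break counter-call chains and anchor phase definitions.
#'
#' @param path Path to the TSV file.
#' @return A tibble `time_s`, `kind`, `note`, sorted by time.
#' @export
read_behavior_table <- function(path) {
  raw <- read_tsv_chr(path)
  missing <- setdiff(c("time_s", "kind"), names(raw))
  if (length(missing) > 0) {
    abort_format(paste0("missing required column \"", missing[1], "\" in ", path),
                 column = missing[1])
  }
  out <- tibble(
    time_s = parse_numeric_col(raw$time_s, "time_s", path),
    kind = tolower(trimws(raw$kind)),
    note = if ("note" %in% names(raw)) raw$note else NA_character_
  )
  validate_behaviors(out)
  dplyr::arrange(out, .data$time_s)
}

validate_behaviors <- function(behaviors) {
  if (nrow(behaviors) == 0) return(invisible(behaviors))
  if (any(behaviors$time_s < 0)) {
    abort_validation("behavior times must be >= 0 s")
  }
  bad <- setdiff(unique(behaviors$kind), behavior_kinds)
  if (length(bad) > 0) {
    abort_validation(paste0("unknown behavior kind: ", bad[1]))
  }
  invisible(behaviors)
}

#' Read a phase-interval table
#'
#' TSV with columns `label`, `start_s`, `end_s`. Intervals are half-open
#' `[start_s, end_s)` and must not overlap.
#'
#' @param path Path to the TSV file.
#' @return A tibble `label`, `start_s`, `end_s`, sorted by start.
#' @export
read_phase_table <- function(path) {
  raw <- read_tsv_chr(path)
  missing <- setdiff(c("label", "start_s", "end_s"), names(raw))
  if (length(missing) > 0) {
    abort_format(paste0("missing required column \"", missing[1], "\" in ", path),
                 column = missing[1])
  }
  out <- tibble(
    label = tolower(trimws(raw$label)),
    start_s = parse_numeric_col(raw$start_s, "start_s", path),
    end_s = parse_numeric_col(raw$end_s, "end_s", path)
  )
  validate_phases(out)
  dplyr::arrange(out, .data$start_s)
}

validate_phases <- function(phases) {
  if (nrow(phases) == 0) return(invisible(phases))
  if (any(phases$start_s >= phases$end_s)) {
    abort_validation("phase intervals must have start_s < end_s")
  }
  ord <- order(phases$start_s)
  s <- phases$start_s[ord]; e <- phases$end_s[ord]
  if (any(s[-1] < e[-length(e)])) {
    abort_validation("phase intervals overlap")
  }
  invisible(phases)
}

#' Assign phase labels to time points
#'
#' Maps each time to the label of the unique phase interval containing it,
#' under the half-open `[start_s, end_s)` convention (so a time exactly on a
#' boundary belongs to the interval that starts there). Times covered by no
#' interval map to `"unphased"` — a value, not an error.
#'
#' @param time_s Numeric vector of times (seconds from session start).
#' @param phases Tibble of non-overlapping phase intervals (`label`,
#'   `start_s`, `end_s`).
#' @return Character vector of phase labels, `"unphased"` where uncovered.
#' @examples
#' phases <- tibble::tibble(
#'   label = c("engagement", "agitation"),
#'   start_s = c(0, 60), end_s = c(60, 300)
#' )
#' assign_phase(c(59.999, 60, 1e4), phases)
#' @export
assign_phase <- function(time_s, phases) {
  if (is.null(phases) || nrow(phases) == 0) {
    return(rep("unphased", length(time_s)))
  }
  validate_phases(phases)
  out <- rep("unphased", length(time_s))
  for (i in seq_len(nrow(phases))) {
    inside <- time_s >= phases$start_s[i] & time_s < phases$end_s[i]
    out[inside] <- phases$label[i]
  }
  out
}

#' Assemble a validated playback session
#'
#' Merges call events, behavior events and phase intervals into a single
#' time-ordered session object. Calls are sorted by onset and annotated with
#' the phase containing their onset; calls outside every phase interval are
#' retained with phase `"unphased"` (they are excluded from phase-stratified
#' statistics but kept in whole-series ones).
#'
#' @param calls Tibble of call events (see [read_selection_table()]).
#' @param behaviors Optional tibble of behavior events; `NULL` for none.
#' @param phases Optional tibble of phase intervals; `NULL` for none.
#' @param day `"playback"` or `"control"`.
#' @return A `playback_session` object: a list with elements `calls`
#'   (phase-annotated), `behaviors`, `phases` and `day`.
#' @export
assemble_session <- function(calls, behaviors = NULL, phases = NULL,
                             day = c("playback", "control")) {
  day <- match.arg(day)
  if (is.null(behaviors)) {
    behaviors <- tibble(time_s = numeric(), kind = character(), note = character())
  }
  if (is.null(phases)) {
    phases <- tibble(label = character(), start_s = numeric(), end_s = numeric())
  }
  validate_calls(calls)
  validate_behaviors(behaviors)
  validate_phases(phases)
  calls <- dplyr::arrange(as_tibble(calls), .data$onset_s, .data$offset_s)
  calls$phase <- assign_phase(calls$onset_s, phases)
  structure(
    list(
      calls = calls,
      behaviors = dplyr::arrange(as_tibble(behaviors), .data$time_s),
      phases = dplyr::arrange(as_tibble(phases), .data$start_s),
      day = day
    ),
    class = "playback_session"
  )
}

#' @export
print.playback_session <- function(x, ...) {
  n_e <- sum(x$calls$source == "exemplar")
  n_s <- sum(x$calls$source == "subject")
  cat("<playback_session> day:", x$day, "\n")
  cat("  calls:    ", nrow(x$calls), " (", n_e, " exemplar, ", n_s,
      " subject)\n", sep = "")
  cat("  behaviors:", nrow(x$behaviors), "\n")
  if (nrow(x$phases) > 0) {
    cat("  phases:   ", paste0(x$phases$label, " [", x$phases$start_s, ",",
                               x$phases$end_s, ")", collapse = ", "), "\n")
  } else {
    cat("  phases:    none\n")
  }
  invisible(x)
}

is_playback_session <- function(x) inherits(x, "playback_session")

assert_session <- function(x, arg = "session") {
  if (!is_playback_session(x)) {
    abort_validation(paste0("`", arg, "` must be a playback_session (see assemble_session())"))
  }
  invisible(x)
}
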