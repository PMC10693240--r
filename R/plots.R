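# ggplot2 views of the pipeline's stage outputs.

#' Plot subject latencies as a time series
#'
#' One point per subject-to-subject latency record, indexed by call order,
#' coloured by counter-call status — the raw material of the latency
#' contrasts.
#'
#' @param latency_data Tibble from [latency_dataset()].
#' @return A ggplot object.
#' @export
plot_latency_series <- function(latency_data) {
  df <- dplyr::mutate(
    dplyr::filter(latency_data, .data$day == "playback"),
    index = dplyr::row_number()
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$latency_s,
                                   colour = .data$is_counter_call)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
                                 name = "counter call") +
    ggplot2::labs(x = "latency record (time order)", y = "latency (s)")
}

#' Plot latency distributions by phase and day
#'
#' Boxplots of subject inter-call latencies per phase (control day as its own
#' level), the visual companion of the phase/day contrast model.
#'
#' @param latency_data Tibble from [latency_dataset()].
#' @return A ggplot object.
#' @export
plot_latency_by_phase <- function(latency_data) {
  df <- dplyr::filter(latency_data, .data$phase != "unphased")
  lev <- intersect(c(phase_labels, "control"), unique(df$phase))
  df$phase <- factor(df$phase, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$latency_s)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "latency (s)")
}

#' Plot per-phase match proportions
#'
#' Stacked bars of matched vs unmatched response pairs per phase; phases
#' flagged insufficient are annotated.
#'
#' @param match_counts Tibble from [match_rate_by_phase()].
#' @return A ggplot object.
#' @export
plot_match_rate <- function(match_counts) {
  long <- tidyr::pivot_longer(match_counts, c("n_matched", "n_unmatched"),
                              names_to = "status", values_to = "n")
  long$status <- ifelse(long$status == "n_matched", "matched", "unmatched")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$n,
                                     fill = .data$status)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(values = c(matched = "#2166ac",
                                          unmatched = "grey75")) +
    ggplot2::labs(x = NULL, y = "proportion of pairs", fill = NULL)
}

#' Plot pair discrepancies over the exchange
#'
#' Discrepancy (percentage points between the pair's standardized shares)
#' per response pair in time order, with the match band (discrepancy <= 18)
#' shaded.
#'
#' @param pairs Tibble from [extract_response_pairs()].
#' @return A ggplot object.
#' @export
plot_discrepancy <- function(pairs) {
  df <- dplyr::mutate(pairs, index = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$discrepancy_pp,
                                   colour = .data$phase)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0, ymax = 18,
                      alpha = 0.12, fill = "#2166ac") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "response pair (time order)",
                  y = "latency-ratio discrepancy (pp)")
}
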