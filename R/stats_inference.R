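# GLM contrasts and randomization-based significance.
#
# Families follow the outcome type: count-like outcomes (latencies rounded to
# whole seconds, integer discrepancies) -> negative binomial with log link;
# binary outcomes (matched or not) -> logistic; amplitudes -> Gaussian
# identity. For a single categorical predictor the log-link coefficient of a
# level is exactly the log of its outcome-mean ratio to the reference level,
# whatever the dispersion; the logistic coefficient is exactly the 2x2
# log-odds ratio. Randomization tests exploit those closed forms.

new_playback_glm <- function(family, link, terms, n_obs, dispersion,
                             reference_level, predictor, inestimable = character(),
                             separation = FALSE, model = NULL) {
  structure(
    list(family = family, link = link, terms = terms, n_obs = n_obs,
         dispersion = dispersion, reference_level = reference_level,
         predictor = predictor, inestimable = inestimable,
         separation = separation, model = model),
    class = "playback_glm"
  )
}

#' @export
print.playback_glm <- function(x, ...) {
  cat("<playback_glm> family:", x$family, " link:", x$link,
      " n:", x$n_obs, "\n")
  cat("  reference level:", x$reference_level, "\n")
  print(as.data.frame(x$terms), row.names = FALSE, digits = 4)
  if (x$family == "neg_binomial") cat("  dispersion:", format(x$dispersion, digits = 4), "\n")
  if (length(x$inestimable) > 0) {
    cat("  inestimable levels (<2 obs):", paste(x$inestimable, collapse = ", "), "\n")
  }
  if (isTRUE(x$separation)) cat("  separation detected; Haldane-Anscombe corrected\n")
  invisible(x)
}

#' @rdname tidy.playback_glm
#' @export
tidy.playback_glm <- function(x, exponentiate = FALSE, ...) {
  out <- x$terms
  if (exponentiate) out$estimate <- exp(out$estimate)
  out
}

#' Tidy and summarise fitted playback models
#'
#' `tidy()` returns the per-term coefficient table (`term`, `estimate`,
#' `std.error`, `statistic`, `p.value`); with `exponentiate = TRUE` logistic
#' coefficients become odds ratios and log-link coefficients become rate
#' ratios. `glance()` returns a one-row model summary.
#'
#' @param x A `playback_glm`.
#' @param exponentiate Exponentiate estimates? Default `FALSE`.
#' @param ... Unused.
#' @name tidy.playback_glm
#' @export
glance.playback_glm <- function(x, ...) {
  tibble(family = x$family, link = x$link, n_obs = x$n_obs,
         dispersion = x$dispersion, reference_level = x$reference_level,
         predictor = x$predictor, separation = x$separation)
}

glm_terms <- function(fit, lev_names) {
  sm <- summary(fit)$coefficients
  rows <- rownames(sm)
  keep <- rows != "(Intercept)"
  term <- sub("^g", "", rows[keep])
  tibble(
    term = term,
    estimate = unname(sm[keep, 1]),
    std.error = unname(sm[keep, 2]),
    statistic = unname(sm[keep, 3]),
    p.value = unname(sm[keep, 4])
  )
}

# negative binomial fit with quiet Poisson fallback when theta diverges
# (no overdispersion); coefficients coincide in that regime
fit_nb_quiet <- function(y, g) {
  dat <- data.frame(y = y, g = g)
  nb <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(y ~ g, data = dat),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) NULL
  )
  if (!is.null(nb) && is.finite(nb$theta) && nb$theta < 1e5) {
    return(list(fit = nb, family = "neg_binomial", dispersion = 1 / nb$theta))
  }
  ps <- glm(y ~ g, family = poisson(), data = dat)
  list(fit = ps, family = "neg_binomial", dispersion = 0)
}

prepare_factor <- function(g, reference) {
  g <- factor(g)
  if (!is.null(reference)) {
    if (!reference %in% levels(g)) {
      abort_validation(paste0("reference level \"", reference, "\" not present"))
    }
    g <- stats::relevel(g, ref = reference)
  }
  g
}

#' Fit the latency contrast model
#'
#' Fits a count-family GLM of subject inter-call latencies on a categorical
#' predictor. Latencies are continuous; for the default negative binomial
#' family they are rounded to the nearest whole second (the minimal
#' reconciliation of a continuous outcome with a count family); a Gamma
#' log-link alternative operating on the raw seconds is available via
#' `family = "gamma"`.
#'
#' `predictor = "phase_day"` contrasts the playback phases and, when
#' control-day records are present, the control day (phase label
#' `"control"`); unphased records are dropped. `predictor = "counter_call"`
#' contrasts counter vs non-counter calls across the entire series
#' regardless of phase (unphased records retained).
#'
#' @param data Latency dataset from [latency_dataset()].
#' @param predictor `"phase_day"` or `"counter_call"`.
#' @param family `"nb"` (negative binomial on rounded seconds; Poisson
#'   fallback when the dispersion vanishes) or `"gamma"` (Gamma, log link, raw
#'   seconds; zero latencies nudged to 1 ms).
#' @param reference Reference level; defaults to `"control"` when present,
#'   else `"engagement"`, else the first level (`"phase_day"`), and to
#'   `"non_counter"` (`"counter_call"`).
#' @return A `playback_glm`. Levels with fewer than 2 observations are
#'   dropped from the fit and listed in `$inestimable`.
#' @export
fit_latency_model <- function(data, predictor = c("phase_day", "counter_call"),
                              family = c("nb", "gamma"), reference = NULL) {
  predictor <- match.arg(predictor)
  family <- match.arg(family)

  if (predictor == "phase_day") {
    data <- dplyr::filter(data, .data$phase != "unphased")
    g <- data$phase
    if (is.null(reference)) {
      reference <- if ("control" %in% g) "control"
      else if ("engagement" %in% g) "engagement"
      else sort(unique(g))[1]
    }
  } else {
    g <- ifelse(data$is_counter_call, "counter", "non_counter")
    if (is.null(reference)) reference <- "non_counter"
  }
  y_raw <- data$latency_s

  tab <- table(g)
  inestimable <- names(tab)[tab < 2]
  keep <- !(g %in% inestimable)
  g <- g[keep]; y_raw <- y_raw[keep]
  if (length(unique(g)) < 2) {
    abort_validation("need >= 2 predictor levels with >= 2 observations each")
  }
  g <- prepare_factor(g, reference)

  if (family == "nb") {
    y <- round(y_raw)
    if (all(y == 0)) abort_validation("degenerate fit: all rounded latencies are zero")
    fitted <- fit_nb_quiet(y, g)
    fit <- fitted$fit
    fam <- "neg_binomial"; link <- "log"; disp <- fitted$dispersion
  } else {
    y <- pmax(y_raw, 0.001)
    fit <- glm(y ~ g, family = Gamma(link = "log"))
    fam <- "gamma"; link <- "log"
    disp <- summary(fit)$dispersion
  }
  new_playback_glm(fam, link, glm_terms(fit), length(y), disp,
                   levels(g)[1], predictor, inestimable = inestimable,
                   model = fit)
}

#' Fit the match-proportion model
#'
#' Logistic regression of the binary match flag on phase. Exponentiated
#' coefficients are odds ratios: the factor by which the odds of a
#' latency-ratio match differ between a phase and the reference phase.
#' Phases with fewer than `min_pairs` pairs are excluded (flagged in
#' `$inestimable`). Complete separation (a phase with 0% or 100% matched)
#' leaves the MLE unbounded; in that case the odds ratios are replaced by
#' Haldane-Anscombe corrected contingency-table estimates (0.5 added to every
#' cell) and the fit is flagged `separation = TRUE`.
#'
#' @param pairs Response-pair tibble from [extract_response_pairs()].
#' @param reference Reference phase; default the first phase present in
#'   timeline order of the labels.
#' @param min_pairs Minimum pairs per phase; default 2.
#' @return A `playback_glm` with `family = "logistic"`.
#' @export
fit_match_model <- function(pairs, reference = NULL, min_pairs = 2) {
  counts <- match_rate_by_phase(pairs, min_pairs = min_pairs)
  inestimable <- counts$phase[counts$insufficient]
  pairs <- dplyr::filter(pairs, !.data$phase %in% inestimable)
  if (length(unique(pairs$phase)) < 2) {
    abort_validation("need >= 2 phases with enough pairs for a match contrast")
  }
  if (is.null(reference)) {
    ord <- c(phase_labels, "unphased")
    present <- intersect(ord, unique(pairs$phase))
    reference <- if (length(present) > 0) present[1] else sort(unique(pairs$phase))[1]
  }
  g <- prepare_factor(pairs$phase, reference)
  y <- as.integer(pairs$matched)

  props <- tapply(y, g, mean)
  separation <- any(props %in% c(0, 1))
  fit <- suppressWarnings(glm(y ~ g, family = binomial()))
  terms <- glm_terms(fit)

  if (separation) {
    # Haldane-Anscombe: +0.5 to each cell of each phase-by-matched table
    m <- tapply(y, g, sum); n <- tapply(y, g, length)
    lo <- log((m + 0.5) / (n - m + 0.5))
    est <- lo[-1] - lo[1]
    terms$estimate <- unname(est[terms$term])
    terms$std.error <- NA_real_
    terms$statistic <- NA_real_
    terms$p.value <- NA_real_
  }
  new_playback_glm("logistic", "logit", terms, length(y), NA_real_,
                   levels(g)[1], "phase", inestimable = inestimable,
                   separation = separation, model = fit)
}

#' Fit the amplitude trend model
#'
#' Gaussian identity-link fit of call amplitude (relative dB) on either
#' elapsed session time in minutes (`"time_min"`) or phase (`"phase"`). Used
#' to quantify the amplitude decline as the subject disengages and departs.
#'
#' @param calls Call-event tibble (needs `amplitude_db`, `onset_s` and — for
#'   the phase predictor — `phase`); typically `session$calls` filtered to
#'   the subject.
#' @param predictor `"time_min"` (slope in dB per minute) or `"phase"`
#'   (per-phase contrasts vs the reference).
#' @param reference Reference phase for `predictor = "phase"`; default
#'   `"engagement"` when present.
#' @return A `playback_glm` with `family = "gaussian"`.
#' @export
fit_amplitude_trend <- function(calls, predictor = c("time_min", "phase"),
                                reference = NULL) {
  predictor <- match.arg(predictor)
  calls <- dplyr::filter(calls, !is.na(.data$amplitude_db))
  if (nrow(calls) < 3) {
    abort_validation("need >= 3 calls with amplitude for a trend fit")
  }
  if (predictor == "time_min") {
    x <- calls$onset_s / 60
    fit <- lm(calls$amplitude_db ~ x)
    sm <- summary(fit)$coefficients
    terms <- tibble(
      term = "time_min",
      estimate = sm[2, 1], std.error = sm[2, 2],
      statistic = sm[2, 3], p.value = sm[2, 4]
    )
    return(new_playback_glm("gaussian", "identity", terms, nrow(calls),
                            summary(fit)$sigma^2, "intercept", predictor,
                            model = fit))
  }
  if (!"phase" %in% names(calls)) {
    abort_validation("`calls` needs a phase column for the phase predictor")
  }
  calls <- dplyr::filter(calls, .data$phase != "unphased")
  if (is.null(reference)) {
    reference <- if ("engagement" %in% calls$phase) "engagement"
    else sort(unique(calls$phase))[1]
  }
  g <- prepare_factor(calls$phase, reference)
  fit <- lm(calls$amplitude_db ~ g)
  new_playback_glm("gaussian", "identity", glm_terms(fit), nrow(calls),
                   summary(fit)$sigma^2, levels(g)[1], predictor, model = fit)
}

# exact single-categorical-predictor MLE coefficients (vs reference = first
# level of the factor); NA where the group summary degenerates
group_coefficients <- function(y, g, family) {
  means <- tapply(y, g, mean)
  if (family %in% c("nb", "poisson")) {
    b <- log(means[-1] / means[1])
  } else if (family == "binomial") {
    b <- qlogis(means[-1]) - qlogis(means[1])
  } else {
    b <- means[-1] - means[1]
  }
  b[!is.finite(b)] <- NA_real_
  b
}

#' Randomization test for a regression coefficient
#'
#' Assesses whether an observed group contrast could be spurious by refitting
#' the model on data whose group labels have been permuted uniformly without
#' replacement, `n_permutations` times, and comparing the observed
#' coefficient against the permutation null by absolute value (two-sided).
#' The empirical p-value uses the add-one estimator
#' `(1 + #(|b*| >= |b_obs|)) / (n_valid + 1)`, which can never return 0.
#'
#' For a single categorical predictor the coefficient of each level is
#' available in closed form (log group-mean ratio under a log link, log-odds
#' difference under logit, mean difference under identity) and equals the GLM
#' maximum-likelihood estimate exactly, for any dispersion; permuted-data
#' coefficients are computed that way. Permutations whose coefficient is
#' undefined (e.g. a permuted group with zero mean) are excluded from the
#' denominator; more than 10% failures aborts the procedure.
#'
#' @param data Data frame holding outcome and label columns.
#' @param outcome Name of the outcome column. Counts/latencies should already
#'   be on the fitted scale (e.g. rounded seconds for the count family).
#' @param label_column Name of the categorical label column to permute.
#' @param family `"nb"` (log link; equals Poisson for the point estimate),
#'   `"binomial"` or `"gaussian"`.
#' @param coefficient Which level's coefficient to track (vs the reference =
#'   first factor level). Default: the last level.
#' @param reference Optional reference level.
#' @param n_permutations Number of permutations (>= 1); default 1000.
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @return A `randomization_result`: list with `beta_observed`, `null_betas`,
#'   `p_empirical`, `n_permutations`, `n_failed`, `seed`, `coefficient`,
#'   `family`.
#' @export
randomization_test <- function(data, outcome, label_column,
                               family = c("nb", "binomial", "gaussian"),
                               coefficient = NULL, reference = NULL,
                               n_permutations = 1000, seed = 1) {
  family <- match.arg(family)
  if (n_permutations < 1) abort_validation("n_permutations must be >= 1")
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  g <- prepare_factor(data[[label_column]], reference)
  if (nlevels(g) < 2) abort_validation("label column needs >= 2 levels")

  obs <- group_coefficients(y, g, family)
  if (is.null(coefficient)) coefficient <- names(obs)[length(obs)]
  if (!coefficient %in% names(obs)) {
    abort_validation(paste0("coefficient level \"", coefficient, "\" not found"))
  }
  beta_obs <- unname(obs[coefficient])
  if (is.na(beta_obs)) abort_validation("observed model does not fit (degenerate groups)")

  set.seed(seed)
  null_betas <- vapply(seq_len(n_permutations), function(b) {
    gp <- sample(g)
    unname(group_coefficients(y, gp, family)[coefficient])
  }, numeric(1))

  failed <- is.na(null_betas)
  if (mean(failed) > 0.10) {
    abort_validation(paste0(sum(failed), " of ", n_permutations,
                            " permutation fits failed (> 10%)"))
  }
  valid <- null_betas[!failed]
  p <- (1 + sum(abs(valid) >= abs(beta_obs))) / (length(valid) + 1)
  structure(
    list(beta_observed = beta_obs, null_betas = null_betas,
         p_empirical = p, n_permutations = n_permutations,
         n_failed = sum(failed), seed = seed,
         coefficient = coefficient, family = family),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("<randomization_result>\n")
  cat("  coefficient:", x$coefficient, " (", x$family, ")\n")
  cat("  beta observed:", format(x$beta_observed, digits = 4), "\n")
  cat("  permutations:", x$n_permutations,
      if (x$n_failed > 0) paste0(" (", x$n_failed, " failed)") else "", "\n")
  cat("  empirical p:", format(x$p_empirical, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.randomization_result <- function(x, ...) {
  tibble(coefficient = x$coefficient, beta_observed = x$beta_observed,
         p_empirical = x$p_empirical, n_permutations = x$n_permutations,
         n_failed = x$n_failed, seed = x$seed)
}

#' @export
glance.randomization_result <- function(x, ...) tidy(x)

#' Plot a randomization null distribution
#'
#' Histogram of the permutation null coefficients with the observed
#' coefficient marked; the empirical p-value is the two-sided tail mass at or
#' beyond the mark.
#'
#' @param object A `randomization_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.randomization_result <- function(object, ...) {
  df <- tibble(beta = object$null_betas[!is.na(object$null_betas)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$beta_observed,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "permutation-null coefficient",
      y = "count",
      title = paste0("Randomization null for ", object$coefficient,
                     " (p = ", signif(object$p_empirical, 3), ")")
    )
}
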