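#' Plot choice probabilities over conditioning trials
#'
#' Doctor-choice proportion per trial index with the overall rate as a
#' dashed reference line.
#'
#' @param trials A trial tibble.
#' @return A ggplot object.
#' @export
plot_choice_probabilities <- function(trials) {
  ch <- choice_probabilities(trials)
  ggplot2::ggplot(ch$by_trial,
                  ggplot2::aes(x = .data$trial_index, y = .data$p_doctor)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ch$overall$p_doctor, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Conditioning trial", y = "P(choose doctor)",
                  title = sprintf("Doctor chosen on %.1f%% of trials",
                                  100 * ch$overall$p_doctor)) +
    ggplot2::theme_minimal()
}

#' Plot per-condition rating means and SDs
#'
#' Participant-level means (points) with across-participant means and
#' standard errors (crossbars), per session and condition.
#'
#' @param trials A trial tibble.
#' @return A ggplot object.
#' @export
plot_condition_summaries <- function(trials) {
  s <- condition_summaries(trials)
  g <- s %>%
    group_by(.data$session, .data$condition) %>%
    summarise(m = mean(.data$mean_rating),
              se = sd(.data$mean_rating) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition,
                                  y = .data$mean_rating)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 1) +
    ggplot2::geom_crossbar(
      data = g,
      ggplot2::aes(y = .data$m, ymin = .data$m - .data$se,
                   ymax = .data$m + .data$se),
      width = 0.4, colour = "firebrick") +
    ggplot2::facet_wrap(~session, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Pain rating (% of reference)") +
    ggplot2::theme_minimal()
}

#' Plot predicted versus actual test-session ratings
#'
#' One point per participant and condition; the identity line marks perfect
#' prediction.
#'
#' @param predictions A tibble with `predicted`, `actual_mean` and
#'   `condition` columns (see [run_study()]'s `predictions` output, or join
#'   [predict_test_ratings()] with test-session [condition_summaries()]).
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions) {
  d <- predictions[predictions$condition %in% c("doctor", "pharmacy"), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$actual_mean,
                                  colour = .data$condition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Predicted test rating", y = "Actual test rating",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Trace plot of an observer fit
#'
#' Post-burn-in draws per chain and parameter, for eyeballing mixing.
#'
#' @param object An [fit_observer()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.observer_fit <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$draw, y = .data$value,
                               colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Draw", y = NULL, colour = "Chain") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
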