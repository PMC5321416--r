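#' Choice probabilities over conditioning trials
#'
#' Fraction of participants choosing the doctor at each conditioning trial
#' index, plus the overall doctor/pharmacy split over all conditioning
#' trials.
#'
#' @param trials A trial tibble.
#' @return A list with `by_trial` (tibble: `trial_index`, `n`, `p_doctor`,
#'   `p_pharmacy`) and `overall` (tibble: `n_trials`, `p_doctor`,
#'   `p_pharmacy`).
#' @export
choice_probabilities <- function(trials) {
  cond <- filter_trials(trials, session = "conditioning")
  if (nrow(cond) == 0) abort("No conditioning trials.")
  by_trial <- cond %>%
    group_by(.data$trial_index) %>%
    summarise(n = dplyr::n(),
              p_doctor = mean(.data$choice == "doctor"),
              .groups = "drop") %>%
    mutate(p_pharmacy = 1 - .data$p_doctor) %>%
    arrange(.data$trial_index)
  overall <- tibble(
    n_trials = nrow(cond),
    p_doctor = mean(cond$choice == "doctor"),
    p_pharmacy = mean(cond$choice == "pharmacy")
  )
  list(by_trial = by_trial, overall = overall)
}

#' Per-participant condition summaries
#'
#' Mean and sample SD (n-1 denominator) of pain ratings per participant,
#' session and condition. Singleton cells get `NA` SD.
#'
#' @param trials A trial tibble.
#' @return A tibble `participant_id`, `session`, `condition`, `n_trials`,
#'   `mean_rating`, `sd_rating`.
#' @export
condition_summaries <- function(trials) {
  as_tibble(trials) %>%
    group_by(.data$participant_id, .data$session, condition = .data$choice) %>%
    summarise(n_trials = dplyr::n(),
              mean_rating = mean(.data$pain_rating),
              sd_rating = ifelse(dplyr::n() >= 2, sd(.data$pain_rating),
                                 NA_real_),
              .groups = "drop")
}

#' Paired t-test on per-participant values
#'
#' Two-sided paired t-test, `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1`
#' degrees of freedom, where `d = a - b` over complete pairs.
#'
#' @param values_a,values_b Equal-length per-participant vectors; pairs with
#'   a missing member are dropped.
#' @return A tibble `t_stat`, `df`, `p_two_sided`, `mean_a`, `mean_b`,
#'   `mean_diff`, `n_pairs`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    abort("`values_a` and `values_b` must have equal length.")
  }
  ok <- is.finite(values_a) & is.finite(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) < 2) abort("Need at least 2 complete pairs.")
  if (var(a - b) == 0) {
    abort("Zero variance of paired differences: t statistic undefined.",
          class = "painbayes_degenerate_error")
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p_two_sided = tt$p.value,
    mean_a = mean(a), mean_b = mean(b), mean_diff = mean(a - b),
    n_pairs = length(a)
  )
}

#' Correlation between predicted and actual test ratings
#'
#' Pearson correlation with a two-sided p-value from the t transform, across
#' participants.
#'
#' @param predicted,actual Per-participant predicted and observed test-mean
#'   ratings (>= 3 pairs).
#' @return A tibble `r`, `p_two_sided`, `n`.
#' @export
predicted_vs_actual <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have equal length.")
  }
  ok <- is.finite(predicted) & is.finite(actual)
  x <- predicted[ok]; y <- actual[ok]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance: correlation undefined.",
          class = "painbayes_degenerate_error")
  }
  ct <- cor.test(x, y)
  tibble(r = unname(ct$estimate), p_two_sided = ct$p.value, n = length(x))
}

#' Trend in doctor-choice probability over trials
#'
#' OLS of the per-trial-index doctor-choice proportion on the trial index,
#' with the slope's t-test; a flat (non-significant) slope indicates stable
#' choice behaviour over the conditioning session.
#'
#' @param trials A trial tibble.
#' @return A tibble `slope`, `se`, `t_stat`, `df`, `p_two_sided`, `n_indices`.
#' @export
choice_trend <- function(trials) {
  by_trial <- choice_probabilities(trials)$by_trial
  if (nrow(by_trial) < 3) abort("Need at least 3 trial indices.")
  f <- lm(p_doctor ~ trial_index, data = by_trial)
  s <- summary(f)$coefficients
  tibble(
    slope = s["trial_index", "Estimate"],
    se = s["trial_index", "Std. Error"],
    t_stat = s["trial_index", "t value"],
    df = f$df.residual,
    p_two_sided = s["trial_index", "Pr(>|t|)"],
    n_indices = nrow(by_trial)
  )
}

#' Behavioural statistics report for a study
#'
#' Computes the paradigm's headline behavioural statistics: overall and
#' per-trial choice probabilities with the time trend, per-condition rating
#' means and SDs (participant-level, then averaged across participants), and
#' the paired t-tests — test-session intensity contrasts (doctor vs control,
#' pharmacy vs control, doctor vs pharmacy) and the conditioning-session
#' precision contrast (per-participant rating SD, doctor vs pharmacy).
#'
#' @param trials A trial tibble (validated).
#' @return A list: `choices` (overall tibble), `choice_trend`, `summaries`
#'   (per participant x session x condition), `group_means` (across
#'   participants), `tests` (tibble of labelled paired t-tests).
#' @export
behavior_report <- function(trials) {
  validate_trials(trials)
  ch <- choice_probabilities(trials)
  summaries <- condition_summaries(trials)
  group_means <- summaries %>%
    group_by(.data$session, .data$condition) %>%
    summarise(
      n_participants = dplyr::n(),
      mean_rating = mean(.data$mean_rating),
      sem_rating = sd(.data$mean_rating) / sqrt(dplyr::n()),
      mean_sd = mean(.data$sd_rating, na.rm = TRUE),
      .groups = "drop")

  wide <- function(session_, value) {
    summaries %>%
      filter(.data$session == session_) %>%
      select("participant_id", "condition", value = all_of(value)) %>%
      tidyr::pivot_wider(names_from = "condition", values_from = "value")
  }
  test_means <- wide("test", "mean_rating")
  cond_sds <- wide("conditioning", "sd_rating")
  cond_means <- wide("conditioning", "mean_rating")

  run_test <- function(label, w, a, b) {
    if (!all(c(a, b) %in% names(w))) return(NULL)
    res <- tryCatch(
      paired_t(w[[a]], w[[b]]),
      painbayes_degenerate_error = function(e) tibble(
        t_stat = NA_real_, df = NA_real_, p_two_sided = NA_real_,
        mean_a = mean(w[[a]], na.rm = TRUE),
        mean_b = mean(w[[b]], na.rm = TRUE),
        mean_diff = mean(w[[a]] - w[[b]], na.rm = TRUE),
        n_pairs = sum(is.finite(w[[a]] - w[[b]]))
      ))
    mutate(res, contrast = label, .before = 1)
  }
  tests <- bind_rows(
    run_test("test mean: doctor vs control", test_means, "doctor", "control"),
    run_test("test mean: pharmacy vs control", test_means, "pharmacy", "control"),
    run_test("test mean: doctor vs pharmacy", test_means, "doctor", "pharmacy"),
    run_test("conditioning mean: doctor vs pharmacy", cond_means,
             "doctor", "pharmacy"),
    run_test("conditioning sd: doctor vs pharmacy", cond_sds,
             "doctor", "pharmacy")
  )

  list(choices = ch$overall, choices_by_trial = ch$by_trial,
       choice_trend = choice_trend(trials),
       summaries = summaries, group_means = group_means, tests = tests)
}
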