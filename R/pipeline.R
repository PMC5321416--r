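#' Run the full analysis pipeline and write report files
#'
#' Orchestrates the package's stages over one study: `simulate` (or read
#' trials from `input`), `stats` (behavioural report), `fit` (per-participant
#' MCMC), `predict`, and `compare` (Bayesian observer vs linear baseline),
#' writing CSV/JSON outputs and a consolidated JSON run report under
#' `outdir`. All randomness derives from `seed` through fixed per-stage
#' child seeds, so two runs with the same inputs are identical.
#'
#' @param outdir Output directory (created if needed).
#' @param cfg A [population_config()] for simulation; ignored when `input`
#'   is given.
#' @param input Optional path to a trials CSV to analyse instead of
#'   simulating.
#' @param map A [psych_map()]; `calibrate = TRUE` refits it from the
#'   conditioning data instead.
#' @param hyper A [hyper_priors()].
#' @param config An [mcmc_config()]; its seed is overridden by `seed`.
#' @param seed Master seed for the run.
#' @param stages Which stages to run after data are available.
#' @param calibrate Calibrate the psychophysical map from the data.
#' @return Invisibly, a list with the stage outputs (`trials`, `stats`,
#'   `estimates`, `predictions`, `comparison`) and the report path.
#' @export
run_study <- function(outdir, cfg = paper_like_config(), input = NULL,
                      map = default_map(), hyper = hyper_priors(),
                      config = mcmc_config(), seed = 1,
                      stages = c("stats", "fit", "predict", "compare"),
                      calibrate = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(outdir, f)
  report <- list(seed = seed, stages = as.list(stages),
                 package_version = as.character(utils::packageVersion("painbayes")))

  if (is.null(input)) {
    sim <- simulate_trust_game(cfg, seed = child_seed(seed, 11))
    trials <- sim$trials
    write_trials(trials, out_path("trials.csv"))
    truth_out <- sim$truth
    truth_out$sigma_prior[is.infinite(truth_out$sigma_prior)] <- NA_real_
    readr::write_csv(truth_out, out_path("ground_truth.csv"), progress = FALSE)
    report$simulate <- list(n_participants = cfg$n_participants,
                            n_conditioning_trials = cfg$n_conditioning_trials,
                            n_test_trials = cfg$n_test_trials,
                            response = cfg$response)
  } else {
    trials <- read_trials(input)
    report$input <- input
  }

  if (calibrate) {
    cal <- calibrate_map(trials)
    map <- cal$map
    report$map <- list(source = "calibrated", slope = map$slope,
                       intercept = map$intercept,
                       residual_sd = cal$residual_sd)
  } else {
    report$map <- list(source = "fixed", slope = map$slope,
                       intercept = map$intercept)
  }

  out <- list(trials = trials, report_path = out_path("report.json"))

  if ("stats" %in% stages) {
    stats_rep <- behavior_report(trials)
    readr::write_csv(stats_rep$choices_by_trial,
                     out_path("choice_probabilities.csv"), progress = FALSE)
    readr::write_csv(stats_rep$summaries, out_path("condition_summaries.csv"),
                     progress = FALSE)
    report$stats <- list(
      choices = as.list(stats_rep$choices),
      choice_trend = as.list(stats_rep$choice_trend),
      group_means = stats_rep$group_means,
      tests = stats_rep$tests
    )
    out$stats <- stats_rep
  }

  estimates <- NULL
  if (any(c("fit", "predict", "compare") %in% stages)) {
    cfg_fit <- config
    cfg_fit$seed <- child_seed(seed, 12)
    estimates <- fit_study(trials, map = map, hyper = hyper, config = cfg_fit)
    readr::write_csv(estimates, out_path("estimates.csv"), progress = FALSE)
    report$fit <- list(n_fits = nrow(estimates),
                       rhat_max = max(estimates$rhat_max),
                       all_converged = all(estimates$converged))
    out$estimates <- estimates
  }

  if (any(c("predict", "compare") %in% stages)) {
    predictions <- predict_test_ratings(estimates, map = map) %>%
      left_join(select(estimates, "participant_id", "condition", "pred_test"),
                by = c("participant_id", "condition")) %>%
      mutate(predicted = dplyr::coalesce(.data$pred_test, .data$predicted)) %>%
      select(-"pred_test")
    actual <- condition_summaries(filter_trials(trials, session = "test")) %>%
      select("participant_id", "condition", actual_mean = "mean_rating")
    predictions <- left_join(predictions, actual,
                             by = c("participant_id", "condition"))
    readr::write_csv(predictions, out_path("predictions.csv"),
                     progress = FALSE)
    cors <- predictions %>%
      filter(.data$condition %in% c("doctor", "pharmacy")) %>%
      group_by(.data$condition) %>%
      group_modify(~ predicted_vs_actual(.x$predicted, .x$actual_mean)) %>%
      ungroup()
    report$predict <- list(correlations = cors)
    out$predictions <- predictions
  }

  if ("compare" %in% stages) {
    comparison <- compare_study(trials, map = map, hyper = hyper,
                                estimates = estimates)
    readr::write_csv(comparison$pooled, out_path("model_comparison.csv"),
                     progress = FALSE)
    jsonlite::write_json(comparison$pooled,
                         out_path("model_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    report$compare <- comparison$pooled
    out$comparison <- comparison
  }

  jsonlite::write_json(report, out_path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(out)
}
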