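#' Linear-regression baseline
#'
#' The comparison model regresses the pain rating on the estimated sensory
#' intensity, `sensation_mean(stimulus_weight, map)`, over one participant's
#' conditioning trials of one choice condition. The pharmacy arm delivers a
#' single stimulus (256 mN), so its design matrix is rank-deficient: by
#' default this is an error; with `allow_degenerate = TRUE` an
#' intercept-only fit (prediction = mean conditioning rating) is returned
#' and flagged, which is the only way the baseline extends to that arm.
#'
#' @param trials Conditioning trials of one participant and condition
#'   (>= 3 rows).
#' @param map A [psych_map()].
#' @param allow_degenerate Fall back to intercept-only when all sensations
#'   are identical.
#' @return An object of class `linear_baseline`: `slope`, `intercept`,
#'   `residual_sd` (n-2 denominator), `n`, `degenerate`, `exact_fit`.
#' @export
fit_linear <- function(trials, map = default_map(), allow_degenerate = FALSE) {
  if (nrow(trials) < 3) abort("Linear baseline needs at least 3 trials.")
  x <- sensation_mean(trials$stimulus_weight, map)
  y <- trials$pain_rating
  degenerate <- length(unique(x)) < 2
  if (degenerate && !allow_degenerate) {
    abort("All sensations identical: slope is not estimable (set allow_degenerate = TRUE for an intercept-only fit).",
          class = "painbayes_rank_deficiency_error")
  }
  if (degenerate) {
    res <- y - mean(y)
    out <- list(slope = 0, intercept = mean(y),
                residual_sd = sqrt(sum(res^2) / (length(y) - 1)))
  } else {
    f <- lm(y ~ x)
    out <- list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
                residual_sd = sqrt(sum(f$residuals^2) / (length(y) - 2)))
  }
  structure(c(out, list(n = length(y), degenerate = degenerate,
                        exact_fit = out$residual_sd < 1e-10, map = list(map))),
            class = "linear_baseline")
}

#' @export
print.linear_baseline <- function(x, ...) {
  cat(sprintf(
    "<linear_baseline> rating = %.4f + %.4f * sensation (residual sd %.4f, n = %d%s)\n",
    x$intercept, x$slope, x$residual_sd, x$n,
    if (x$degenerate) ", intercept-only" else ""))
  invisible(x)
}

#' @rdname fit_linear
#' @param object A `linear_baseline`.
#' @param weight Stimulus force in mN at which to predict.
#' @param ... Unused.
#' @export
predict.linear_baseline <- function(object, weight = 512, ...) {
  object$intercept + object$slope * sensation_mean(weight, object$map[[1]])
}

#' Root-mean-square prediction error
#'
#' @param predicted,actual Equal-length numeric vectors of ratings.
#' @return `sqrt(mean((predicted - actual)^2))`.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(predicted) == 0) {
    abort("`predicted` and `actual` must have equal nonzero length.")
  }
  sqrt(mean((predicted - actual)^2))
}

#' Prediction-error BIC
#'
#' Bayesian information criterion computed from *test-session prediction
#' residuals* under a Gaussian error model:
#' `n * ln(SSE / n) + k * ln(n)`. This follows the study procedure of
#' scoring models by their out-of-session prediction error rather than the
#' textbook training-likelihood BIC; lower is better. A perfect prediction
#' (SSE = 0) has no finite value under this form and raises an error.
#'
#' @inheritParams rmse
#' @param k_params Number of model parameters charged to the model.
#' @return The BIC value (scalar).
#' @export
bic <- function(predicted, actual, k_params) {
  if (length(predicted) != length(actual) || length(predicted) == 0) {
    abort("`predicted` and `actual` must have equal nonzero length.")
  }
  stopifnot(k_params >= 1)
  n <- length(predicted)
  sse <- sum((predicted - actual)^2)
  if (sse <= 0) {
    abort("SSE = 0: perfect prediction has no finite prediction-error BIC.",
          class = "painbayes_degenerate_fit_error")
  }
  n * log(sse / n) + k_params * log(n)
}

#' Compare Bayesian-observer and linear-baseline predictions
#'
#' Scores both models' predictions of the same test-session ratings with
#' RMSE and the prediction-error [bic()], and flags the winner (lower BIC).
#'
#' @param bayes_predicted,linear_predicted,actual Aligned rating vectors
#'   over identical test trials.
#' @param k_bayes,k_linear Parameters charged to each model (default 3 each:
#'   prior mean, prior SD and sensory SD for the observer; slope, intercept
#'   and residual SD for the baseline).
#' @param condition Optional label carried into the output.
#' @return A tibble with one row per model: `model`, `condition`,
#'   `n_test_trials`, `rmse`, `bic`, `k_params`, `winner`.
#' @export
compare_models <- function(bayes_predicted, linear_predicted, actual,
                           k_bayes = 3, k_linear = 3, condition = NA_character_) {
  if (length(bayes_predicted) != length(actual) ||
      length(linear_predicted) != length(actual)) {
    abort("Prediction and actual vectors must be aligned.")
  }
  out <- tibble(
    model = c("bayesian", "linear"),
    condition = condition,
    n_test_trials = length(actual),
    rmse = c(rmse(bayes_predicted, actual), rmse(linear_predicted, actual)),
    bic = c(bic(bayes_predicted, actual, k_bayes),
            bic(linear_predicted, actual, k_linear)),
    k_params = c(k_bayes, k_linear)
  )
  out$winner <- if (out$bic[1] == out$bic[2]) "tie" else
    out$model[which.min(out$bic)]
  out
}

#' End-to-end model comparison on a study
#'
#' Fits the Bayesian observer ([fit_study()]) and the per-participant linear
#' baselines ([fit_linear()]) on the conditioning session, predicts every
#' test-session trial of the doctor and pharmacy conditions, and pools
#' prediction residuals within condition across participants (the headline
#' comparison); a per-participant decomposition is returned alongside.
#'
#' @inheritParams fit_study
#' @param estimates Optional precomputed [fit_study()] result (skips the
#'   MCMC stage).
#' @param k_bayes,k_linear Parameter counts charged to each model.
#' @return A list with `pooled` (tibble: model x condition RMSE/BIC),
#'   `per_participant` (same metrics per participant) and `predictions`
#'   (per-trial tibble with both models' predictions and the actual rating).
#' @export
compare_study <- function(trials, map = default_map(), hyper = hyper_priors(),
                          config = mcmc_config(), estimates = NULL,
                          k_bayes = 3, k_linear = 3) {
  validate_trials(trials)
  if (is.null(estimates)) {
    estimates <- fit_study(trials, map = map, hyper = hyper, config = config)
  }
  # posterior-mean predictions when available (fit_study supplies them);
  # otherwise fall back to plugging point estimates into the fusion
  bayes_pred <- if ("pred_test" %in% names(estimates)) {
    select(estimates, "participant_id", "condition", predicted = "pred_test")
  } else {
    predict_test_ratings(estimates, map = map, control_prior = NULL)
  }

  cond_trials <- filter_trials(trials, session = "conditioning")
  linear_pred <- cond_trials %>%
    filter(.data$choice %in% c("doctor", "pharmacy")) %>%
    group_by(.data$participant_id, condition = .data$choice) %>%
    group_modify(~ tibble(predicted_linear = predict(
      fit_linear(.x, map = map, allow_degenerate = TRUE), weight = 512))) %>%
    ungroup()

  test_trials <- filter_trials(trials, session = "test",
                               choice = c("doctor", "pharmacy"))
  predictions <- test_trials %>%
    select("participant_id", condition = "choice", "trial_index",
           actual = "pain_rating") %>%
    left_join(rename(bayes_pred, predicted_bayes = "predicted"),
              by = c("participant_id", "condition")) %>%
    left_join(linear_pred, by = c("participant_id", "condition")) %>%
    select("participant_id", "condition", "trial_index", "actual",
           "predicted_bayes", "predicted_linear")
  if (anyNA(predictions$predicted_bayes) || anyNA(predictions$predicted_linear)) {
    abort("Some test trials have no prediction (condition never chosen during conditioning).")
  }

  pooled <- predictions %>%
    group_by(.data$condition) %>%
    group_modify(~ select(compare_models(.x$predicted_bayes,
                                         .x$predicted_linear, .x$actual,
                                         k_bayes, k_linear), -"condition")) %>%
    ungroup() %>%
    select("model", "condition", "n_test_trials", "rmse", "bic", "k_params",
           "winner")

  per_participant <- predictions %>%
    group_by(.data$participant_id, .data$condition) %>%
    group_modify(~ select(compare_models(.x$predicted_bayes,
                                         .x$predicted_linear, .x$actual,
                                         k_bayes, k_linear), -"condition")) %>%
    ungroup() %>%
    select("participant_id", "model", "condition", "n_test_trials", "rmse",
           "bic", "k_params", "winner")

  list(pooled = pooled, per_participant = per_participant,
       predictions = predictions, estimates = estimates)
}
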