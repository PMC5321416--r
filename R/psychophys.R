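#' Logarithmic stimulus-to-sensation map
#'
#' Mechanical pain from the weighted-needle stimulator grows approximately
#' linearly in the logarithm of the applied force, so the mean felt
#' intensity of a `weight` mN stimulus is modelled as
#' `slope * ln(weight) + intercept`, in rating units (percent of the
#' reference pain). The natural logarithm is used throughout; any other base
#' is absorbed into the coefficients.
#'
#' `default_map()` anchors the map to sensation(64 mN) = 7.5 and
#' sensation(256 mN) = 57.5 rating units, i.e. slope `50/ln 4` and intercept
#' `-142.5`, which puts the reference stimulus at sensation(512 mN) = 82.5.
#'
#' @param slope Rating units per log-mN; must be positive for a calibrated
#'   map (sensation increases with force).
#' @param intercept Rating units.
#' @return An object of class `psych_map`.
#' @examples
#' m <- default_map()
#' sensation_mean(c(64, 256, 512), m)
#' @export
psych_map <- function(slope, intercept) {
  stopifnot(is.numeric(slope), length(slope) == 1, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1, is.finite(intercept))
  structure(list(slope = slope, intercept = intercept), class = "psych_map")
}

#' @rdname psych_map
#' @export
default_map <- function() psych_map(50 / log(4), -142.5)

#' @export
print.psych_map <- function(x, ...) {
  cat(sprintf("<psych_map> sensation(w) = %.4f * ln(w) + %.4f\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Mean sensation of a stimulus
#'
#' @param weight Stimulus force in mN; must be positive. Vectorised.
#' @param map A [psych_map()].
#' @return Mean sensation in rating units.
#' @export
sensation_mean <- function(weight, map = default_map()) {
  stopifnot(inherits(map, "psych_map"))
  if (any(!is.finite(weight) | weight <= 0)) {
    abort("`weight` must be positive and finite.")
  }
  map$slope * log(weight) + map$intercept
}

#' Calibrate the stimulus-to-sensation map from conditioning trials
#'
#' Ordinary least squares of pain rating on `ln(stimulus_weight)` over
#' conditioning-session trials. With `per_participant = TRUE` a separate map
#' is fitted per participant (each needs two distinct stimulus weights, i.e.
#' doctor trials at both 64 and 256 mN).
#'
#' @param trials A trial tibble; only conditioning-session rows are used.
#' @param per_participant Fit one map per participant instead of a pooled map.
#' @return For a pooled fit, a list with elements `map` ([psych_map()]),
#'   `residual_sd` and `n`. For per-participant fits, a tibble with one row
#'   per participant and columns `participant_id`, `slope`, `intercept`,
#'   `residual_sd`, `n`.
#' @export
calibrate_map <- function(trials, per_participant = FALSE) {
  cond <- filter_trials(trials, session = "conditioning")
  if (per_participant) {
    cond %>%
      group_by(.data$participant_id) %>%
      summarise(fit = list(calibrate_one(.data$stimulus_weight, .data$pain_rating)),
                .groups = "drop") %>%
      tidyr::unnest_wider("fit")
  } else {
    f <- calibrate_one(cond$stimulus_weight, cond$pain_rating)
    list(map = psych_map(f$slope, f$intercept),
         residual_sd = f$residual_sd, n = f$n)
  }
}

calibrate_one <- function(weight, rating) {
  if (length(unique(weight)) < 2) {
    abort("Calibration needs at least two distinct stimulus weights.",
          class = "painbayes_rank_deficiency_error")
  }
  fit <- lm(rating ~ log(weight))
  s <- if (length(rating) > 2) sqrt(sum(fit$residuals^2) / (length(rating) - 2)) else 0
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       residual_sd = s, n = length(rating))
}
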