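#' Gaussian beliefs over perceived pain
#'
#' A belief is a Normal distribution in rating units, used for the
#' condition-specific prior over pain, the sensory likelihood, and the
#' fused posterior. A flat (uninformative) belief is represented by
#' `sigma = Inf` via [flat_belief()].
#'
#' @param mu Mean, rating units.
#' @param sigma Standard deviation, rating units; `> 0`, or `Inf` for a flat
#'   belief.
#' @return An object of class `gaussian_belief`.
#' @examples
#' fuse(gaussian_belief(50, 10), gaussian_belief(90, 20))
#' @export
gaussian_belief <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1,
            is.numeric(sigma), length(sigma) == 1)
  if (is.infinite(sigma)) return(flat_belief())
  if (!is.finite(mu)) abort("`mu` must be finite for a proper belief.")
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
  structure(list(mu = mu, sigma = sigma, flat = FALSE),
            class = "gaussian_belief")
}

#' @rdname gaussian_belief
#' @export
flat_belief <- function() {
  structure(list(mu = NA_real_, sigma = Inf, flat = TRUE),
            class = "gaussian_belief")
}

#' @rdname gaussian_belief
#' @param x A `gaussian_belief`.
#' @export
is_flat <- function(x) {
  stopifnot(inherits(x, "gaussian_belief"))
  isTRUE(x$flat)
}

#' @export
print.gaussian_belief <- function(x, ...) {
  if (is_flat(x)) cat("<gaussian_belief> flat (sigma = Inf)\n")
  else cat(sprintf("<gaussian_belief> Normal(mu = %.4g, sigma = %.4g)\n",
                   x$mu, x$sigma))
  invisible(x)
}

#' Fuse two Gaussian beliefs (prior x likelihood)
#'
#' Precision-weighted combination of a prior expectation over pain with
#' sensory evidence: the posterior precision is the sum of the input
#' precisions, `1/sigma_post^2 = 1/sigma_prior^2 + 1/sigma_s^2`, and the
#' posterior mean is the precision-weighted average of the input means. The
#' operation is symmetric in its arguments; fusing with a flat belief
#' returns the other belief unchanged.
#'
#' @param prior,likelihood [gaussian_belief()] objects; at most one flat.
#' @return The posterior `gaussian_belief`.
#' @export
fuse <- function(prior, likelihood) {
  stopifnot(inherits(prior, "gaussian_belief"),
            inherits(likelihood, "gaussian_belief"))
  if (is_flat(prior) && is_flat(likelihood)) {
    abort("Cannot fuse two flat beliefs: the posterior is undefined.",
          class = "painbayes_flat_fusion_error")
  }
  if (is_flat(prior)) return(likelihood)
  if (is_flat(likelihood)) return(prior)
  p1 <- 1 / prior$sigma^2
  p2 <- 1 / likelihood$sigma^2
  gaussian_belief(
    mu = (prior$mu * p1 + likelihood$mu * p2) / (p1 + p2),
    sigma = sqrt(1 / (p1 + p2))
  )
}

#' Observer parameters for one participant-condition
#'
#' Bundles the learned condition prior over pain, the sensory noise, and
#' the psychophysical map — everything needed to predict a rating for a
#' given stimulus.
#'
#' @param prior A [gaussian_belief()]: the condition-specific prior
#'   Pr(pain | condition). May be flat (e.g. for control trials, where no
#'   conditioning data exist).
#' @param sensory_sigma Sensory noise SD in rating units, `> 0`.
#' @param map A [psych_map()].
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(prior, sensory_sigma, map = default_map()) {
  stopifnot(inherits(prior, "gaussian_belief"), inherits(map, "psych_map"))
  if (!is.finite(sensory_sigma) || sensory_sigma <= 0) {
    abort("`sensory_sigma` must be > 0.")
  }
  structure(list(prior = prior, sensory_sigma = sensory_sigma, map = map),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n  prior: ")
  print(x$prior)
  cat(sprintf("  sensory_sigma: %.4g\n  map: slope %.4f, intercept %.4f\n",
              x$sensory_sigma, x$map$slope, x$map$intercept))
  invisible(x)
}

#' Predict the pain rating for a stimulus
#'
#' Fuses the observer's condition prior with the sensory likelihood centred
#' on [sensation_mean()] of the stimulus. The returned belief's mean is the
#' point prediction (posterior mean) and its SD the predictive spread.
#'
#' @param params An [observer_params()].
#' @param weight Stimulus force in mN, `> 0` (scalar).
#' @return A [gaussian_belief()]: the posterior over perceived pain.
#' @export
predict_rating <- function(params, weight) {
  stopifnot(inherits(params, "observer_params"), length(weight) == 1)
  lik <- gaussian_belief(sensation_mean(weight, params$map),
                         params$sensory_sigma)
  fuse(params$prior, lik)
}
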