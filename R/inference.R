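#' Hyperpriors for observer-parameter estimation
#'
#' Weakly informative hyperpriors on the 0-100 magnitude-estimation scale:
#' the prior mean over pain gets a wide Normal, and both standard deviations
#' (prior width and sensory noise) get half-Normals.
#'
#' @param mu_location,mu_scale Normal hyperprior on the condition prior mean
#'   (rating units).
#' @param sigma_prior_scale Half-Normal scale for the prior SD.
#' @param sigma_s_scale Half-Normal scale for the sensory noise SD.
#' @return An object of class `hyper_priors`.
#' @export
hyper_priors <- function(mu_location = 50, mu_scale = 50,
                         sigma_prior_scale = 30, sigma_s_scale = 30) {
  stopifnot(mu_scale > 0, sigma_prior_scale > 0, sigma_s_scale > 0)
  structure(list(mu_location = mu_location, mu_scale = mu_scale,
                 sigma_prior_scale = sigma_prior_scale,
                 sigma_s_scale = sigma_s_scale),
            class = "hyper_priors")
}

#' MCMC sampler settings
#'
#' Settings for the component-wise random-walk Metropolis sampler used by
#' [fit_observer()]. `n_samples` is the total number of sweeps per chain;
#' the first `burn_in` sweeps are discarded and used to adapt the
#' per-parameter proposal scales towards a 20-40% acceptance rate.
#'
#' @param n_chains Number of chains (>= 2, for convergence diagnostics).
#' @param n_samples Total sweeps per chain (burn-in included).
#' @param burn_in Sweeps discarded and used for adaptation; `< n_samples`.
#' @param proposal_scale Initial random-walk SD for every parameter.
#' @param seed Integer seed; all chain randomness derives from it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_samples = 5000, burn_in = 1000,
                        proposal_scale = 5, seed = 1) {
  stopifnot(n_chains >= 2, burn_in >= 1, burn_in < n_samples,
            proposal_scale > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in),
                 proposal_scale = proposal_scale,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

half_normal_logpdf <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2) + dnorm(x, 0, scale, log = TRUE))
}

#' Log joint density of observer parameters for one condition
#'
#' The observation model reads each rated trial as a draw from the fused
#' posterior of that trial: `rating ~ Normal(mu_post, sigma_post)`, where
#' `mu_post` fuses the candidate condition prior `(mu_prior, sigma_prior)`
#' with the trial's sensory likelihood
#' `(sensation_mean(weight, map), sigma_s)`. The returned value is the sum
#' of per-trial log-likelihoods plus the hyperprior log-densities; a
#' non-positive SD candidate yields `-Inf` (rejected), not an error. With
#' zero trials only the hyperprior density remains.
#'
#' @param theta Named numeric vector with elements `mu_prior`, `sigma_prior`,
#'   `sigma_s`.
#' @param trials Conditioning trials of one participant and condition (may
#'   have zero rows).
#' @param map A [psych_map()].
#' @param hyper A [hyper_priors()].
#' @return The log density (scalar; may be `-Inf`).
#' @export
log_joint <- function(theta, trials, map = default_map(),
                      hyper = hyper_priors()) {
  mu <- theta[["mu_prior"]]; sp <- theta[["sigma_prior"]]; ss <- theta[["sigma_s"]]
  lp <- dnorm(mu, hyper$mu_location, hyper$mu_scale, log = TRUE) +
    half_normal_logpdf(sp, hyper$sigma_prior_scale) +
    half_normal_logpdf(ss, hyper$sigma_s_scale)
  if (!is.finite(lp)) return(-Inf)
  if (nrow(trials) > 0) {
    mu_s <- sensation_mean(trials$stimulus_weight, map)
    lp <- lp + loglik_condition(trials$pain_rating, mu_s, mu, sp, ss)
  }
  lp
}

# Gaussian fused-response log-likelihood for one condition's trials.
loglik_condition <- function(ratings, mu_s, mu, sp, ss) {
  if (sp <= 0 || ss <= 0) return(-Inf)
  w <- sp^2 / (sp^2 + ss^2)                 # weight on the sensory mean
  sigma_post <- sqrt(w) * ss                # since sigma_post^2 = w * ss^2
  sum(dnorm(ratings, w * mu_s + (1 - w) * mu, sigma_post, log = TRUE))
}

# ---- sampler internals ------------------------------------------------------

# Parameter layout for a joint per-participant fit over one or two
# conditions, optionally sharing sigma_s across conditions.
param_layout <- function(conditions, share_sigma_s) {
  nm <- c(rbind(paste0("mu_", conditions), paste0("sigma_", conditions)))
  if (share_sigma_s) c(nm, "sigma_s") else c(nm, paste0("sigma_s_", conditions))
}

# Compiled description of the per-participant joint model: parameter vector
# layout, per-condition data, which conditions each parameter touches, and
# the hyperprior of each parameter. Everything is indexed by integer position
# so the chain loop stays cheap.
build_model <- function(data_by_cond, conditions, share_sigma_s, hyper) {
  params <- param_layout(conditions, share_sigma_s)
  idx <- setNames(seq_along(params), params)
  conds <- lapply(seq_along(conditions), function(j) {
    cond <- conditions[j]
    d <- data_by_cond[[cond]]
    list(
      ratings = d$ratings, mu_s = d$mu_s, n = length(d$ratings),
      i_mu = idx[[paste0("mu_", cond)]],
      i_sp = idx[[paste0("sigma_", cond)]],
      i_ss = if (share_sigma_s) idx[["sigma_s"]] else
        idx[[paste0("sigma_s_", cond)]]
    )
  })
  # conditions whose likelihood a parameter enters
  affected <- lapply(params, function(p) {
    which(vapply(conds, function(cn)
      idx[[p]] %in% c(cn$i_mu, cn$i_sp, cn$i_ss), TRUE))
  })
  hyper_lp <- lapply(params, function(p) {
    if (startsWith(p, "mu_")) {
      loc <- hyper$mu_location; sc <- hyper$mu_scale
      function(x) -log(sc) - 0.5 * log(2 * pi) - 0.5 * ((x - loc) / sc)^2
    } else {
      sc <- if (startsWith(p, "sigma_s")) hyper$sigma_s_scale else
        hyper$sigma_prior_scale
      function(x) if (x <= 0) -Inf else
        log(2) - log(sc) - 0.5 * log(2 * pi) - 0.5 * (x / sc)^2
    }
  })
  list(params = params, idx = idx, conds = conds, affected = affected,
       hyper_lp = hyper_lp)
}

cond_loglik <- function(cn, theta) {
  sp <- theta[cn$i_sp]; ss <- theta[cn$i_ss]
  if (sp <= 0 || ss <= 0) return(-Inf)
  w <- sp * sp / (sp * sp + ss * ss)
  v_post <- w * ss * ss
  resid <- cn$ratings - (w * cn$mu_s + (1 - w) * theta[cn$i_mu])
  -0.5 * cn$n * log(2 * pi * v_post) - sum(resid * resid) / (2 * v_post)
}

run_chain <- function(model, init, free_idx, config, chain_seed) {
  withr::with_seed(chain_seed, {
    theta <- init
    conds <- model$conds
    hyper_lp <- model$hyper_lp
    affected <- model$affected
    cl <- vapply(conds, cond_loglik, 0, theta = theta)
    hl <- vapply(seq_along(theta), function(k) hyper_lp[[k]](theta[k]), 0)
    if (!all(is.finite(c(cl, hl[free_idx])))) {
      abort("Initial state has zero density.")
    }
    n_free <- length(free_idx)
    n_keep <- config$n_samples - config$burn_in
    kept <- matrix(NA_real_, n_keep, length(theta),
                   dimnames = list(NULL, model$params))
    ld_trace <- numeric(n_keep)
    scales <- rep(config$proposal_scale, n_free)
    acc <- win <- numeric(n_free)
    acc_post <- n_post <- numeric(n_free)
    for (i in seq_len(config$n_samples)) {
      adapting <- i <= config$burn_in
      for (f in seq_len(n_free)) {
        p <- free_idx[f]
        prop_val <- theta[p] + rnorm(1) * scales[f]
        new_h <- hyper_lp[[p]](prop_val)
        accepted <- FALSE
        if (new_h > -Inf) {
          aff <- affected[[p]]
          old_val <- theta[p]
          theta[p] <- prop_val
          new_cl <- cl
          delta <- new_h - hl[p]
          for (j in aff) {
            new_cl[j] <- cond_loglik(conds[[j]], theta)
            delta <- delta + new_cl[j] - cl[j]
          }
          if (is.finite(delta) && log(runif(1)) < delta) {
            accepted <- TRUE
            hl[p] <- new_h
            cl <- new_cl
          } else {
            theta[p] <- old_val
          }
        }
        if (adapting) {
          acc[f] <- acc[f] + accepted; win[f] <- win[f] + 1
          if (win[f] == 50) {          # steer towards 20-40% acceptance
            scales[f] <- scales[f] * exp(acc[f] / 50 - 0.3)
            acc[f] <- win[f] <- 0
          }
        } else {
          acc_post[f] <- acc_post[f] + accepted
          n_post[f] <- n_post[f] + 1
        }
      }
      if (!adapting) {
        kept[i - config$burn_in, ] <- theta
        ld_trace[i - config$burn_in] <- sum(cl) + sum(hl[free_idx])
      }
    }
    list(draws = kept, log_density = ld_trace,
         accept_rate = setNames(acc_post / pmax(n_post, 1),
                                model$params[free_idx]),
         scales = scales)
  })
}

# Split-Rhat: each chain is halved, then the classical potential scale
# reduction factor is computed over the 2 * n_chains half-chains.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Effective sample size via Geyer's initial positive sequence on the
# chain-averaged autocorrelation.
ess_basic <- function(chains) {
  n <- length(chains[[1]]); m <- length(chains)
  lag_max <- min(n - 1, 1000)
  acov <- function(x) {
    if (var(x) == 0) return(c(0, numeric(lag_max)))
    drop(stats::acf(x, lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf)
  }
  g <- Reduce(`+`, lapply(chains, acov)) / m
  if (g[1] == 0) return(n * m)
  rho <- g / g[1]
  tau <- 1; k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, m * n / tau)
}

#' Fit the Bayesian observer to one participant's conditioning trials
#'
#' Estimates the condition-specific prior over pain (mean and SD) and the
#' sensory noise SD by component-wise random-walk Metropolis. By default the
#' two choice conditions (doctor, pharmacy) are fitted jointly with a single
#' shared sensory-noise channel `sigma_s`; this joint design is what makes
#' the pharmacy arm (a single conditioning stimulus) identifiable, because
#' the doctor arm's two stimulus levels pin down the fusion weight and hence
#' `sigma_s`. Draws are reproducible bit-for-bit under a fixed
#' `config$seed`.
#'
#' @param trials Conditioning trials of a single participant (rows from
#'   other sessions are ignored).
#' @param map A [psych_map()].
#' @param hyper A [hyper_priors()].
#' @param config An [mcmc_config()].
#' @param conditions Conditions to fit; defaults to the choice conditions
#'   present in the data.
#' @param share_sigma_s Share `sigma_s` across conditions (default) or give
#'   each condition its own.
#' @param fix Named list of parameters to hold fixed (e.g.
#'   `list(sigma_doctor = 20, sigma_s = 10)`); fixed parameters are not
#'   sampled.
#' @return An object of class `observer_fit` with elements `draws` (long
#'   tibble: chain, draw, parameter, value), `summary` (per-parameter
#'   posterior mean, sd, 95% credible interval, split-Rhat, effective sample
#'   size), `accept_rate`, `log_density`, `conditions`, `map`, `fixed`,
#'   `config`, and `n_trials`.
#' @export
fit_observer <- function(trials, map = default_map(), hyper = hyper_priors(),
                         config = mcmc_config(), conditions = NULL,
                         share_sigma_s = TRUE, fix = list()) {
  cond_trials <- filter_trials(trials, session = "conditioning")
  if (nrow(cond_trials) == 0) abort("No conditioning trials to fit.")
  if (length(unique(cond_trials$participant_id)) != 1) {
    abort("`fit_observer()` fits one participant at a time; use `fit_study()`.")
  }
  if (is.null(conditions)) {
    conditions <- intersect(c("doctor", "pharmacy"),
                            unique(cond_trials$choice))
  }
  if (length(conditions) == 0) abort("No choice conditions present.")

  data_by_cond <- lapply(setNames(conditions, conditions), function(cond) {
    d <- cond_trials[cond_trials$choice == cond, ]
    list(ratings = d$pain_rating,
         mu_s = sensation_mean(d$stimulus_weight, map))
  })

  model <- build_model(data_by_cond, conditions, share_sigma_s, hyper)
  params <- model$params
  if (!all(names(fix) %in% params)) {
    abort(paste0("Unknown fixed parameter(s): ",
                 paste(setdiff(names(fix), params), collapse = ", ")))
  }
  free <- setdiff(params, names(fix))
  if (length(free) == 0) abort("All parameters fixed; nothing to sample.")
  free_idx <- model$idx[free]

  chains <- lapply(seq_len(config$n_chains), function(ch) {
    init <- withr::with_seed(child_seed(config$seed, 101, ch), {
      ini <- setNames(numeric(length(params)), params)
      for (cond in conditions) {
        r <- data_by_cond[[cond]]$ratings
        centre <- if (length(r) > 0) mean(r) else hyper$mu_location
        ini[[paste0("mu_", cond)]] <- rnorm(1, centre, 15)
        ini[[paste0("sigma_", cond)]] <- runif(1, 3, 40)
      }
      ss_names <- grep("^sigma_s", params, value = TRUE)
      for (s in ss_names) ini[[s]] <- runif(1, 3, 40)
      for (p in names(fix)) ini[[p]] <- fix[[p]]
      ini
    })
    run_chain(model, init, free_idx, config, child_seed(config$seed, 202, ch))
  })

  summary_tbl <- purrr::map_dfr(free, function(p) {
    per_chain <- lapply(chains, function(ch) ch$draws[, p])
    all_draws <- unlist(per_chain)
    tibble(
      parameter = p,
      mean = mean(all_draws), sd = sd(all_draws),
      q2.5 = unname(quantile(all_draws, 0.025)),
      q97.5 = unname(quantile(all_draws, 0.975)),
      rhat = split_rhat(per_chain),
      ess = ess_basic(per_chain)
    )
  })
  if (length(fix) > 0) {
    summary_tbl <- bind_rows(summary_tbl, tibble(
      parameter = names(fix), mean = unlist(fix), sd = 0,
      q2.5 = unlist(fix), q97.5 = unlist(fix), rhat = NA_real_, ess = NA_real_
    ))
  }
  accept <- colMeans(do.call(rbind, lapply(chains, `[[`, "accept_rate")))
  if (any(accept == 0)) {
    abort(paste0("Pathological chain: no accepted proposals for ",
                 paste(names(accept)[accept == 0], collapse = ", ")),
          class = "painbayes_mcmc_error")
  }
  rhat_max <- max(summary_tbl$rhat, na.rm = TRUE)
  if (is.finite(rhat_max) && rhat_max > 1.05) {
    warn(sprintf("MCMC may not have converged: max split-Rhat = %.3f",
                 rhat_max))
  }

  draws <- purrr::map_dfr(seq_along(chains), function(ch) {
    k <- chains[[ch]]$draws[, free, drop = FALSE]
    tibble(chain = ch, draw = rep(seq_len(nrow(k)), times = length(free)),
           parameter = rep(free, each = nrow(k)), value = as.vector(k))
  })

  structure(list(
    draws = draws, summary = summary_tbl, accept_rate = accept,
    log_density = lapply(chains, `[[`, "log_density"),
    conditions = conditions, share_sigma_s = share_sigma_s,
    map = map, fixed = fix, config = config,
    participant_id = cond_trials$participant_id[1],
    n_trials = nrow(cond_trials)
  ), class = "observer_fit")
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("<observer_fit> participant %s, %d conditioning trials, %s\n",
              x$participant_id, x$n_trials,
              paste(x$conditions, collapse = " + ")))
  print(x$summary)
  invisible(x)
}

#' @rdname fit_observer
#' @param x An `observer_fit`.
#' @param ... Unused.
#' @export
tidy.observer_fit <- function(x, ...) x$summary

#' @rdname fit_observer
#' @export
glance.observer_fit <- function(x, ...) {
  tibble(
    n_trials = x$n_trials,
    n_chains = x$config$n_chains,
    n_draws = x$config$n_chains * (x$config$n_samples - x$config$burn_in),
    rhat_max = max(x$summary$rhat, na.rm = TRUE),
    ess_min = min(x$summary$ess, na.rm = TRUE),
    converged = max(x$summary$rhat, na.rm = TRUE) <= 1.05
  )
}

#' Build observer parameters from a fitted model
#'
#' Projects posterior-mean point estimates of one condition out of an
#' [fit_observer()] result. Refuses (with diagnostics) when the fit has not
#' converged, unless `allow_nonconverged = TRUE`.
#'
#' @param fit An `observer_fit`.
#' @param condition One of the fitted conditions.
#' @param rhat_threshold Convergence threshold on split-Rhat.
#' @param allow_nonconverged Override the convergence refusal.
#' @return An [observer_params()].
#' @export
extract_observer <- function(fit, condition = fit$conditions[1],
                             rhat_threshold = 1.05,
                             allow_nonconverged = FALSE) {
  stopifnot(inherits(fit, "observer_fit"))
  if (!condition %in% fit$conditions) {
    abort(paste0("Condition '", condition, "' was not fitted."))
  }
  rhat_max <- max(fit$summary$rhat, na.rm = TRUE)
  if (is.finite(rhat_max) && rhat_max > rhat_threshold && !allow_nonconverged) {
    abort(sprintf(
      "Fit has not converged (max split-Rhat %.3f > %.2f); pass allow_nonconverged = TRUE to override.",
      rhat_max, rhat_threshold), class = "painbayes_convergence_error")
  }
  est <- setNames(fit$summary$mean, fit$summary$parameter)
  ss_name <- if (fit$share_sigma_s) "sigma_s" else paste0("sigma_s_", condition)
  observer_params(
    prior = gaussian_belief(est[[paste0("mu_", condition)]],
                            est[[paste0("sigma_", condition)]]),
    sensory_sigma = est[[ss_name]],
    map = fit$map
  )
}

#' Posterior-mean prediction of the rating at a stimulus
#'
#' The Bayes point prediction of a rated stimulus under squared loss: the
#' fused-posterior mean `w * sensation + (1 - w) * mu_prior` (with
#' `w = sigma_prior^2 / (sigma_prior^2 + sigma_s^2)`) averaged over the MCMC
#' draws, which integrates over parameter uncertainty instead of plugging in
#' point estimates — the distinction matters because the fusion weight is a
#' non-linear function of the two (right-skewed) variance parameters.
#'
#' @param fit An [fit_observer()] result.
#' @param weight Stimulus force in mN (scalar).
#' @param conditions Conditions to predict (default: all fitted).
#' @return A tibble `condition`, `weight`, `predicted` (posterior mean of
#'   the fused mean), `predicted_sd` (posterior SD of the fused mean, i.e.
#'   parameter uncertainty only, not the sensory spread).
#' @export
predict_posterior <- function(fit, weight = 512, conditions = fit$conditions) {
  stopifnot(inherits(fit, "observer_fit"), length(weight) == 1)
  mu_s <- sensation_mean(weight, fit$map)
  wide <- tidyr::pivot_wider(fit$draws, names_from = "parameter",
                             values_from = "value")
  get_par <- function(p) {
    if (p %in% names(wide)) wide[[p]] else rep(fit$fixed[[p]], nrow(wide))
  }
  purrr::map_dfr(conditions, function(cond) {
    mu <- get_par(paste0("mu_", cond))
    sp <- get_par(paste0("sigma_", cond))
    ss <- get_par(if (fit$share_sigma_s) "sigma_s" else
      paste0("sigma_s_", cond))
    w <- sp^2 / (sp^2 + ss^2)
    pred <- w * mu_s + (1 - w) * mu
    tibble(condition = cond, weight = weight,
           predicted = mean(pred), predicted_sd = sd(pred))
  })
}

#' Fit the observer model to every participant in a study
#'
#' Runs [fit_observer()] per participant on the conditioning session, with a
#' deterministic per-participant seed derived from `config$seed`, and
#' collects posterior-mean estimates, 95% credible intervals and
#' convergence diagnostics in one tibble (one row per participant and
#' condition).
#'
#' @inheritParams fit_observer
#' @param trials A full study's trials.
#' @param keep_fits Attach the individual `observer_fit` objects as a
#'   list-column `fit`.
#' @param test_weight Stimulus (mN) at which the posterior-mean test
#'   prediction `pred_test` is computed (see [predict_posterior()]).
#' @return A tibble with columns `participant_id`, `condition`, `mu_prior`,
#'   `mu_prior_lo`, `mu_prior_hi`, `sigma_prior`, `sigma_prior_lo`,
#'   `sigma_prior_hi`, `sigma_s`, `sigma_s_lo`, `sigma_s_hi`, `pred_test`,
#'   `rhat_max`, `ess_min`, `converged` (+ optional `fit`).
#' @export
fit_study <- function(trials, map = default_map(), hyper = hyper_priors(),
                      config = mcmc_config(), share_sigma_s = TRUE,
                      fix = list(), keep_fits = FALSE, test_weight = 512) {
  validate_trials(trials)
  ids <- sort(unique(trials$participant_id))
  purrr::map_dfr(seq_along(ids), function(i) {
    pt <- filter_trials(trials, session = "conditioning", participant = ids[i])
    cfg_i <- config
    cfg_i$seed <- child_seed(config$seed, 303, i)
    fit <- fit_observer(pt, map = map, hyper = hyper, config = cfg_i,
                        share_sigma_s = share_sigma_s, fix = fix)
    est <- fit$summary
    g <- glance(fit)
    pp <- predict_posterior(fit, weight = test_weight)
    purrr::map_dfr(fit$conditions, function(cond) {
      ss_name <- if (share_sigma_s) "sigma_s" else paste0("sigma_s_", cond)
      row_of <- function(p) est[est$parameter == p, ]
      mu <- row_of(paste0("mu_", cond)); sp <- row_of(paste0("sigma_", cond))
      ss <- row_of(ss_name)
      out <- tibble(
        participant_id = ids[i], condition = cond,
        mu_prior = mu$mean, mu_prior_lo = mu$q2.5, mu_prior_hi = mu$q97.5,
        sigma_prior = sp$mean, sigma_prior_lo = sp$q2.5,
        sigma_prior_hi = sp$q97.5,
        sigma_s = ss$mean, sigma_s_lo = ss$q2.5, sigma_s_hi = ss$q97.5,
        pred_test = pp$predicted[pp$condition == cond],
        rhat_max = g$rhat_max, ess_min = g$ess_min, converged = g$converged
      )
      if (keep_fits) out$fit <- list(fit)
      out
    })
  })
}

#' Predict test-session ratings from fitted observer parameters
#'
#' Fuses each row's estimated prior with the sensory likelihood of the test
#' stimulus (512 mN by default). A `control` row is added with the supplied
#' control prior (flat by default: no conditioning data exist for control
#' trials, so its prediction is the bare sensation).
#'
#' @param estimates A tibble as returned by [fit_study()] (needs
#'   `participant_id`, `condition`, `mu_prior`, `sigma_prior`, `sigma_s`).
#' @param map A [psych_map()].
#' @param weight Test stimulus force in mN.
#' @param control_prior A [gaussian_belief()] used for the control
#'   prediction, or `NULL` to omit control rows.
#' @param control_sigma_s Sensory noise for the control prediction; defaults
#'   to each participant's mean fitted `sigma_s`.
#' @return A tibble `participant_id`, `condition`, `predicted`, `predicted_sd`.
#' @export
predict_test_ratings <- function(estimates, map = default_map(), weight = 512,
                                 control_prior = flat_belief(),
                                 control_sigma_s = NULL) {
  fitted_rows <- purrr::pmap_dfr(
    estimates[, c("participant_id", "condition", "mu_prior", "sigma_prior",
                  "sigma_s")],
    function(participant_id, condition, mu_prior, sigma_prior, sigma_s) {
      params <- observer_params(gaussian_belief(mu_prior, sigma_prior),
                                sigma_s, map)
      post <- predict_rating(params, weight)
      tibble(participant_id = participant_id, condition = condition,
             predicted = post$mu, predicted_sd = post$sigma)
    })
  if (is.null(control_prior)) return(fitted_rows)
  control_rows <- estimates %>%
    group_by(.data$participant_id) %>%
    summarise(sigma_s = mean(.data$sigma_s), .groups = "drop") %>%
    mutate(
      condition = "control",
      predicted = purrr::map_dbl(.data$sigma_s, function(ss) {
        ss <- if (is.null(control_sigma_s)) ss else control_sigma_s
        predict_rating(observer_params(control_prior, ss, map), weight)$mu
      }),
      predicted_sd = purrr::map_dbl(.data$sigma_s, function(ss) {
        ss <- if (is.null(control_sigma_s)) ss else control_sigma_s
        predict_rating(observer_params(control_prior, ss, map), weight)$sigma
      })
    ) %>%
    select("participant_id", "condition", "predicted", "predicted_sd")
  bind_rows(fitted_rows, control_rows) %>%
    arrange(.data$participant_id, .data$condition)
}
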