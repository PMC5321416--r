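test_that("log_joint reduces to the hyperprior density with zero trials", {
  hp <- hyper_priors()
  empty <- make_tiny_trials()[0, ]
  theta <- c(mu_prior = 45, sigma_prior = 12, sigma_s = 9)
  expected <- dnorm(45, 50, 50, log = TRUE) +
    log(2) + dnorm(12, 0, 30, log = TRUE) +
    log(2) + dnorm(9, 0, 30, log = TRUE)
  expect_equal(log_joint(theta, empty, hyper = hp), expected)
})

test_that("log_joint matches a hand-computed single-trial value", {
  map <- default_map()
  trial <- tibble::tibble(
    participant_id = "a", session = "conditioning", trial_index = 1,
    choice = "doctor", stimulus_weight = 256, pain_rating = 50, cost = 2
  )
  theta <- c(mu_prior = 40, sigma_prior = 10, sigma_s = 10)
  w <- 0.5
  mu_post <- w * 57.5 + (1 - w) * 40          # 48.75
  s_post <- sqrt(0.5) * 10
  expected <- dnorm(50, mu_post, s_post, log = TRUE) +
    dnorm(40, 50, 50, log = TRUE) +
    2 * (log(2) + dnorm(10, 0, 30, log = TRUE))
  expect_equal(log_joint(theta, trial, map), expected)
})

test_that("doubling the data doubles the log-likelihood term", {
  trials <- make_participant_trials(40, 10, 10, seed = 4)
  theta <- c(mu_prior = 38, sigma_prior = 11, sigma_s = 9)
  hp <- hyper_priors()
  prior_part <- log_joint(theta, trials[0, ], hyper = hp)
  ll1 <- log_joint(theta, trials, hyper = hp) - prior_part
  doubled <- dplyr::mutate(dplyr::bind_rows(trials, trials),
                           trial_index = dplyr::row_number())
  ll2 <- log_joint(theta, doubled, hyper = hp) - prior_part
  expect_equal(ll2, 2 * ll1)
})

test_that("non-positive sigma candidates yield -Inf, not an error", {
  trials <- make_participant_trials(40, 10, 10, seed = 4)
  expect_identical(log_joint(c(mu_prior = 40, sigma_prior = -1, sigma_s = 10),
                             trials), -Inf)
  expect_identical(log_joint(c(mu_prior = 40, sigma_prior = 10, sigma_s = 0),
                             trials), -Inf)
})

test_that("MCMC matches the closed-form conjugate posterior of mu_prior", {
  map <- default_map()
  for (s in 1:2) {
    trials <- make_participant_trials(mu_prior = 35 + 10 * s,
                                      sigma_prior = 20, sigma_s = 10,
                                      n_doctor = 30, n_pharmacy = 0, seed = s)
    fit <- fit_observer(trials, map = map,
                        config = mcmc_config(n_chains = 2, n_samples = 3000,
                                             burn_in = 500, seed = 100 + s),
                        conditions = "doctor",
                        fix = list(sigma_doctor = 20, sigma_s = 10))
    got <- fit$summary[fit$summary$parameter == "mu_doctor", ]
    oracle <- conjugate_mu_posterior(
      trials$pain_rating, sensation_mean(trials$stimulus_weight, map),
      sigma_prior = 20, sigma_s = 10)
    mcse_mean <- got$sd / sqrt(got$ess)
    mcse_sd <- got$sd / sqrt(2 * (got$ess - 1))
    expect_lt(abs(got$mean - oracle["mean"]), 3 * mcse_mean)
    expect_lt(abs(got$sd - oracle["sd"]), 3 * mcse_sd)
  }
})

test_that("a fixed seed reproduces the draw sequence bit for bit", {
  trials <- make_participant_trials(40, 10, 10, seed = 8)
  f1 <- suppressWarnings(fit_observer(trials, config = light_mcmc(seed = 5)))
  f2 <- suppressWarnings(fit_observer(trials, config = light_mcmc(seed = 5)))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_observer(trials, config = light_mcmc(seed = 6)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("extract_observer projects point estimates and guards convergence", {
  trials <- make_participant_trials(40, 10, 10, seed = 8)
  fit <- suppressWarnings(fit_observer(trials, config = light_mcmc(seed = 5)))
  obs <- extract_observer(fit, "doctor", allow_nonconverged = TRUE)
  est <- setNames(fit$summary$mean, fit$summary$parameter)
  expect_equal(obs$prior$mu, unname(est["mu_doctor"]))
  expect_equal(obs$prior$sigma, unname(est["sigma_doctor"]))
  expect_equal(obs$sensory_sigma, unname(est["sigma_s"]))

  # a fit whose diagnostics exceed the threshold is refused
  bad <- fit
  bad$summary$rhat <- 2
  expect_error(extract_observer(bad, "doctor"),
               class = "painbayes_convergence_error")
  expect_error(extract_observer(fit, "control"), "not fitted")
})

test_that("posterior of sigma_prior tightens with more conditioning data", {
  sds <- vapply(1:3, function(s) {
    widths <- vapply(c(10, 60), function(n) {
      trials <- make_participant_trials(40, 10, 10, n_doctor = n,
                                        n_pharmacy = 0, seed = s)
      fit <- suppressWarnings(
        fit_observer(trials, config = light_mcmc(seed = s),
                     conditions = "doctor", fix = list(sigma_s = 10)))
      fit$summary$sd[fit$summary$parameter == "sigma_doctor"]
    }, 0)
    widths
  }, c(0, 0))
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("end-to-end: fit, extract and predict reproduces the generator", {
  truth <- list(mu = 45, sp = 12, ss = 10)
  trials <- make_participant_trials(truth$mu, truth$sp, truth$ss,
                                    n_doctor = 60, n_pharmacy = 60, seed = 3)
  fit <- suppressWarnings(
    fit_observer(trials, config = mcmc_config(n_chains = 2, n_samples = 2500,
                                              burn_in = 500, seed = 9)))
  obs <- extract_observer(fit, "doctor", allow_nonconverged = TRUE)
  w <- truth$sp^2 / (truth$sp^2 + truth$ss^2)
  true_pred <- w * 82.5 + (1 - w) * truth$mu
  expect_equal(predict_rating(obs, 512)$mu, true_pred, tolerance = 0.12)
  pp <- predict_posterior(fit, 512, conditions = "doctor")
  expect_equal(pp$predicted, true_pred, tolerance = 0.12)
})

test_that("pathological data and empty inputs raise informative errors", {
  trials <- make_participant_trials(40, 10, 10, seed = 8)
  expect_error(fit_observer(trials[0, ]), "No conditioning trials")
  expect_error(fit_observer(trials, fix = list(nonsense = 1)), "Unknown fixed")
  two <- dplyr::bind_rows(trials,
                          dplyr::mutate(trials, participant_id = "other"))
  expect_error(fit_observer(two), "one participant")
})
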