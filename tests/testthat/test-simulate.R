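test_that("sampling the population is reproducible and respects its spread", {
  cfg <- population_config(n_participants = 6)
  t1 <- sample_population(cfg, seed = 3)
  t2 <- sample_population(cfg, seed = 3)
  expect_equal(t1, t2)
  expect_false(isTRUE(all.equal(t1$mu_prior,
                                sample_population(cfg, seed = 4)$mu_prior)))

  # zero between-participant spread makes everyone identical
  cfg0 <- population_config(n_participants = 5, between_sd = 0)
  t0 <- sample_population(cfg0, seed = 1)
  doc <- t0[t0$condition == "doctor", ]
  expect_true(all(doc$mu_prior == doc$mu_prior[1]))

  # law of large numbers: sample means approach the configured means
  big <- sample_population(population_config(n_participants = 10000),
                           seed = 9)
  doc_mu <- mean(big$mu_prior[big$condition == "doctor"])
  expect_lt(abs(doc_mu - 40), 4 * 15 / sqrt(10000))
})

test_that("simulated studies obey the paradigm contingencies", {
  sim <- simulate_trust_game(population_config(n_participants = 10), seed = 2)
  trials <- sim$trials
  expect_silent(validate_trials(trials))
  cond <- filter_trials(trials, session = "conditioning")
  expect_true(all(cond$stimulus_weight[cond$choice == "pharmacy"] == 256))
  expect_true(all(cond$stimulus_weight[cond$choice == "doctor"]
                  %in% c(64, 256)))
  test <- filter_trials(trials, session = "test")
  expect_true(all(test$stimulus_weight == 512))
  expect_setequal(unique(test$choice), c("doctor", "pharmacy", "control"))
  # per participant: 40 conditioning, 3 x 10 test trials
  counts <- table(trials$participant_id, trials$session)
  expect_true(all(counts[, "conditioning"] == 40))
  expect_true(all(counts[, "test"] == 30))
})

test_that("the noiseless flat-prior limit returns the bare sensation", {
  cfg <- population_config(n_participants = 2, n_conditioning_trials = 8,
                           n_test_trials = 2,
                           prior_doctor = c(0, 1e6), prior_pharmacy = c(0, 1e6),
                           sensory_sigma = 1e-9, report_noise_sd = 0)
  trials <- simulate_trust_game(cfg, seed = 5)$trials
  expect_equal(trials$pain_rating,
               sensation_mean(trials$stimulus_weight, cfg$map),
               tolerance = 1e-4)
})

test_that("doctor trials split 50/50 between 64 and 256 mN", {
  cfg <- population_config(n_participants = 250, p_doctor = 0.5,
                           n_test_trials = 1)
  trials <- simulate_trust_game(cfg, seed = 13)$trials
  doc <- filter_trials(trials, session = "conditioning", choice = "doctor")
  frac64 <- mean(doc$stimulus_weight == 64)
  expect_lt(abs(frac64 - 0.5), 1.96 * sqrt(0.25 / nrow(doc)))
})

test_that("the 64/256 stimulus mixture inflates doctor-condition SDs", {
  trials <- simulate_trust_game(paper_like_config(), seed = 6)$trials
  s <- condition_summaries(filter_trials(trials, session = "conditioning"))
  w <- tidyr::pivot_wider(s[, c("participant_id", "condition", "sd_rating")],
                          names_from = "condition", values_from = "sd_rating")
  expect_true(all(w$doctor > w$pharmacy))
})

test_that("test-session condition means follow the configured prior order", {
  cfg <- paper_like_config(n_participants = 40)
  means <- purrr::map_dfr(1:3, function(s) {
    trials <- simulate_trust_game(cfg, seed = 20 + s)$trials
    s <- condition_summaries(filter_trials(trials, session = "test"))
    tidyr::pivot_wider(
      dplyr::summarise(dplyr::group_by(s, condition),
                       m = mean(mean_rating), .groups = "drop"),
      names_from = "condition", values_from = "m")
  })
  expect_true(all(means$doctor < means$control))
  expect_true(all(means$pharmacy < means$control))
})

test_that("linear response mode generates ratings affine in sensation", {
  cfg <- population_config(n_participants = 3, response = "linear",
                           linear_slope = 1, linear_intercept = 0,
                           linear_sd = 1e-9, between_sd = 0,
                           n_test_trials = 2)
  trials <- simulate_trust_game(cfg, seed = 4)$trials
  expect_equal(trials$pain_rating,
               sensation_mean(trials$stimulus_weight, cfg$map),
               tolerance = 1e-4)
})

test_that("recovery scales: fewer conditioning trials inflate mu_prior RMSE", {
  light <- mcmc_config(n_chains = 2, n_samples = 900, burn_in = 250, seed = 1)
  rmse_at <- function(n_trials) {
    mean(vapply(1:2, function(s) {
      cfg <- population_config(n_participants = 6,
                               n_conditioning_trials = n_trials,
                               n_test_trials = 1)
      rec <- suppressWarnings(
        recovery_experiment(cfg, light, seed = 30 + s))
      mean(rec$summary$rmse[rec$summary$parameter == "mu_prior"])
    }, 0))
  }
  expect_lt(rmse_at(40), rmse_at(8))
})
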