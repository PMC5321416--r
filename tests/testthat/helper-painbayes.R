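# Shared fixtures and independent oracles, all built in code.

# Numerical-integration oracle for Gaussian fusion: normalize the product of
# the two densities on a dense grid and read off its mean and sd.
grid_fuse <- function(mu1, s1, mu2, s2, n = 40001) {
  lo <- min(mu1 - 10 * s1, mu2 - 10 * s2)
  hi <- max(mu1 + 10 * s1, mu2 + 10 * s2)
  x <- seq(lo, hi, length.out = n)
  d <- dnorm(x, mu1, s1) * dnorm(x, mu2, s2)
  d <- d / sum(d)
  m <- sum(x * d)
  c(mean = m, sd = sqrt(sum((x - m)^2 * d)))
}

# Closed-form normal-normal conjugate posterior of mu_prior when sigma_prior
# and sigma_s are fixed: each rating is Normal((1-w)*mu + w*mu_s_t, s_post),
# a linear-Gaussian model with coefficient (1-w) on mu.
conjugate_mu_posterior <- function(ratings, mu_s, sigma_prior, sigma_s,
                                   mu0 = 50, tau0 = 50) {
  w <- sigma_prior^2 / (sigma_prior^2 + sigma_s^2)
  v_post <- w * sigma_s^2
  cc <- 1 - w
  prec <- 1 / tau0^2 + length(ratings) * cc^2 / v_post
  mean <- (mu0 / tau0^2 + cc * sum(ratings - w * mu_s) / v_post) / prec
  c(mean = mean, sd = sqrt(1 / prec))
}

# A tiny hand-built valid study: 2 participants, conditioning + test.
make_tiny_trials <- function() {
  tibble::tibble(
    participant_id = rep(c("a", "b"), each = 7),
    session = rep(c(rep("conditioning", 4), rep("test", 3)), 2),
    trial_index = rep(c(1:4, 1:3), 2),
    choice = rep(c("doctor", "doctor", "pharmacy", "pharmacy",
                   "doctor", "pharmacy", "control"), 2),
    stimulus_weight = rep(c(64, 256, 256, 256, 512, 512, 512), 2),
    pain_rating = c(10, 50, 55, 60, 80, 85, 95,
                    12, 48, 57, 59, 78, 88, 93),
    cost = rep(c(2, 2, 1, 1, 2, 1, 0), 2)
  )
}

# Conditioning trials for a single synthetic participant with a known
# generative observer, drawn directly from the fused response model.
make_participant_trials <- function(mu_prior, sigma_prior, sigma_s,
                                    n_doctor = 20, n_pharmacy = 20,
                                    map = default_map(), seed = 1) {
  withr::with_seed(seed, {
    weight <- c(sample(c(64, 256), n_doctor, replace = TRUE),
                rep(256, n_pharmacy))
    choice <- rep(c("doctor", "pharmacy"), c(n_doctor, n_pharmacy))
    mu_s <- sensation_mean(weight, map)
    w <- sigma_prior^2 / (sigma_prior^2 + sigma_s^2)
    rating <- rnorm(length(weight), w * mu_s + (1 - w) * mu_prior,
                    sqrt(w) * sigma_s)
    tibble::tibble(
      participant_id = "sim", session = "conditioning",
      trial_index = seq_along(weight), choice = choice,
      stimulus_weight = weight, pain_rating = pmax(rating, 0),
      cost = ifelse(choice == "doctor", 2, 1)
    )
  })
}

# Small sampler settings for unit tests.
light_mcmc <- function(seed = 1) {
  mcmc_config(n_chains = 2, n_samples = 1200, burn_in = 300, seed = seed)
}
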