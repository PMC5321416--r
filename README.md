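# painbayes

Bayesian observer modelling of placebo analgesia induced by **instrumental
conditioning**, for researchers in computational psychophysics and
pain/placebo science.

In the underlying paradigm — a "medical trust game" — a participant receives
a painful 512 mN reference stimulus on every trial, then chooses between a
costly **doctor** treatment (pain drops to 64 or 256 mN with 50% probability
each: large relief, low precision) and a cheap **pharmacy** treatment (pain
always drops to 256 mN: smaller relief, high precision), and rates the
second stimulus relative to the reference (magnitude estimation,
reference = 100). After 40 conditioning trials, the test session always
delivers the full 512 mN stimulus; ratings below the no-choice control
trials are placebo analgesia, produced by the learned expectation alone.

## The model

Perceived pain is the precision-weighted fusion of a learned
condition-specific prior with noisy sensory evidence whose mean is affine in
log stimulus force:

```
Pr(P | C)    ~  Normal(mu_prior, sigma_prior)         (condition prior)
Pr(S | P)    ~  Normal(a ln(weight) + b, sigma_s)     (sensory likelihood)
Pr(P | C, S) ~  Normal(mu_post, sigma_post)           (percept = posterior)

1/sigma_post^2 = 1/sigma_prior^2 + 1/sigma_s^2
mu_post        = sigma_post^2 (mu_prior/sigma_prior^2 + mu_s/sigma_s^2)
```

Per participant, the condition priors and the (shared) sensory noise are
estimated from conditioning-session ratings by random-walk Metropolis MCMC;
the fitted observer predicts test-session ratings, and is compared against a
per-participant linear-regression baseline with RMSE and a prediction-error
BIC (`n ln(SSE/n) + k ln(n)` on held-out test residuals, lower is better).
A synthetic-study generator with known ground truth makes the whole pipeline
testable end to end; see the methods vignette
(`vignettes/observer-model.Rmd`) for the model's assumptions, defaults and
limitations.

## Worked example

```r
library(painbayes)

# Gaussian fusion: prior (50, 10) x likelihood (90, 20)
fuse(gaussian_belief(50, 10), gaussian_belief(90, 20))
#> <gaussian_belief> Normal(mu = 58, sigma = 8.944)

# simulate a 24-participant study in the regime anchored to the published
# summary statistics, then run the behavioural analyses
sim <- simulate_trust_game(paper_like_config(), seed = 1)
rep <- behavior_report(sim$trials)

rep$choices
#>   n_trials p_doctor p_pharmacy
#> 1      960    0.398      0.602

rep$tests[, c("contrast", "t_stat", "df", "p_two_sided")]
#>   contrast                              t_stat    df p_two_sided
#> 1 test mean: doctor vs control          -13.7     23    1.42e-12
#> 2 test mean: pharmacy vs control        -13.1     23    3.80e-12
#> 3 test mean: doctor vs pharmacy          -2.46    23    2.17e- 2
#> 4 conditioning mean: doctor vs pharmacy -18.4     23    3.07e-15
#> 5 conditioning sd: doctor vs pharmacy    19.6     23    7.88e-16
```

Participants rate the identical 512 mN test stimulus as less painful after
choosing either treatment than on control trials (placebo analgesia), and
doctor-choice conditioning ratings have much larger per-participant SDs than
pharmacy ones — the low-precision 64/256 mN mixture at work.

```r
# fit the observer per participant and compare against the linear baseline
est <- fit_study(sim$trials,
                 config = mcmc_config(n_chains = 2, n_samples = 2000,
                                      burn_in = 500, seed = 2))
cmp <- compare_study(sim$trials, estimates = est)
cmp$pooled
#>   model    condition n_test_trials  rmse   bic k_params winner
#> 1 bayesian doctor              240  10.8 1156.        3 bayesian
#> 2 linear   doctor              240  11.7 1198.        3 bayesian
#> 3 bayesian pharmacy            240  10.6 1149.        3 bayesian
#> 4 linear   pharmacy            240  21.5 1490.        3 bayesian
```

The observer out-predicts the linear baseline in both conditions, most
starkly on the pharmacy arm, where a regression on sensation cannot even
estimate a slope (one conditioning stimulus level) while the observer
extrapolates through the fusion weight. `rmse` is in rating units;
`bic` differences matter, not levels.

Other entry points: `read_trials()`/`write_trials()` (CSV schema
`participant_id,session,trial_index,choice,stimulus_weight,pain_rating,cost`),
`calibrate_map()` for the log stimulus-sensation map, `fit_observer()` /
`tidy()` / `glance()` / `autoplot()` for single fits,
`recovery_experiment()` for parameter recovery against ground truth,
`run_study()` to execute every stage and write CSV/JSON reports, and
`plot_choice_probabilities()`, `plot_condition_summaries()`,
`plot_predictions()` for figures.

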