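test_that("choice probabilities normalize and handle degenerate datasets", {
  trials <- make_tiny_trials()
  ch <- choice_probabilities(trials)
  expect_true(all(ch$by_trial$p_doctor + ch$by_trial$p_pharmacy == 1))
  expect_true(all(ch$by_trial$p_doctor >= 0 & ch$by_trial$p_doctor <= 1))

  all_doc <- trials
  all_doc$choice[all_doc$session == "conditioning"] <- "doctor"
  all_doc$stimulus_weight[all_doc$session == "conditioning"] <- 64
  expect_true(all(choice_probabilities(all_doc)$by_trial$p_doctor == 1))
})

test_that("simulated choice rate sits inside binomial bounds of p_doctor", {
  cfg <- population_config(n_participants = 50, n_conditioning_trials = 40)
  trials <- simulate_trust_game(cfg, seed = 17)$trials
  ch <- choice_probabilities(trials)$overall
  n <- ch$n_trials
  half_width <- 1.96 * sqrt(0.403 * 0.597 / n)
  expect_lt(abs(ch$p_doctor - 0.403), half_width)
})

test_that("condition summaries match hand-computed mean and sample SD", {
  trials <- make_tiny_trials()
  s <- condition_summaries(trials)
  row <- s[s$participant_id == "a" & s$session == "conditioning" &
             s$condition == "doctor", ]
  expect_equal(row$n_trials, 2L)
  expect_equal(row$mean_rating, 30)            # (10 + 50) / 2
  expect_equal(row$sd_rating, sd(c(10, 50)))   # n-1 denominator
  # singleton cells get NA sd
  ctl <- s[s$condition == "control" & s$participant_id == "a", ]
  expect_true(is.na(ctl$sd_rating))
  # constant ratings give SD 0
  const <- trials
  const$pain_rating <- 42
  expect_true(all(condition_summaries(const)$sd_rating %in% c(0, NA)))
  # permutation invariance
  perm <- trials[sample(nrow(trials)), ]
  expect_equal(dplyr::arrange(condition_summaries(perm),
                              participant_id, session, condition),
               dplyr::arrange(s, participant_id, session, condition))
})

test_that("paired_t matches the hand-worked example and t.test identities", {
  r <- paired_t(c(5, 7, 9), c(4, 5, 9))
  expect_equal(r$t_stat, sqrt(3))
  expect_equal(r$df, 2)
  expect_equal(r$p_two_sided, 2 * pt(sqrt(3), 2, lower.tail = FALSE))

  # identical vectors are degenerate (zero difference variance)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)),
               class = "painbayes_degenerate_error")

  # sign flip negates t, preserves p
  a <- c(10, 14, 9, 20); b <- c(8, 15, 7, 12)
  r1 <- paired_t(a, b); r2 <- paired_t(b, a)
  expect_equal(r1$t_stat, -r2$t_stat)
  expect_equal(r1$p_two_sided, r2$p_two_sided)
})

test_that("paired_t and predicted_vs_actual match closed forms on random data", {
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(3:25, 1)
      a <- rnorm(n, 50, 15); b <- rnorm(n, 45, 15)
      d <- a - b
      t_manual <- mean(d) / (sd(d) / sqrt(n))
      r <- paired_t(a, b)
      expect_equal(r$t_stat, t_manual)
      expect_equal(r$df, n - 1)
      expect_equal(r$p_two_sided, 2 * pt(abs(t_manual), n - 1,
                                         lower.tail = FALSE))

      rho_manual <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
      cr <- predicted_vs_actual(a, b)
      expect_equal(cr$r, rho_manual)
      t_r <- rho_manual * sqrt((n - 2) / (1 - rho_manual^2))
      expect_equal(cr$p_two_sided, 2 * pt(abs(t_r), n - 2,
                                          lower.tail = FALSE))
    }
  })
})

test_that("predicted_vs_actual hits the exact-correlation limits", {
  x <- c(1, 5, 9, 13)
  expect_equal(predicted_vs_actual(x, x)$r, 1)
  expect_equal(predicted_vs_actual(x, -x + 100)$r, -1)
  expect_error(predicted_vs_actual(x, rep(2, 4)),
               class = "painbayes_degenerate_error")
  expect_error(predicted_vs_actual(x[1:2], x[1:2]), "at least 3")
})

test_that("choice_trend is flat for constant series and signed for ramps", {
  mk <- function(p_by_index) {
    n_idx <- length(p_by_index)
    purrr::map_dfr(1:40, function(pid) tibble::tibble(
      participant_id = sprintf("p%02d", pid), session = "conditioning",
      trial_index = seq_len(n_idx),
      # participant pid chooses doctor at index t iff pid/41 < p_by_index[t],
      # so the per-index doctor proportion tracks p_by_index
      choice = ifelse(pid / 41 < p_by_index, "doctor", "pharmacy"),
      stimulus_weight = 256, pain_rating = 50, cost = 1
    ))
  }
  flat <- suppressWarnings(choice_trend(mk(rep(0.5, 20))))  # exact fit
  expect_equal(flat$slope, 0, tolerance = 1e-10)

  rising <- choice_trend(mk(seq(0.1, 0.9, length.out = 20)))
  expect_gt(rising$slope, 0)
  expect_lt(rising$p_two_sided, 0.01)
})

test_that("stationary choices rarely produce a significant trend", {
  hits <- vapply(1:100, function(s) {
    trials <- simulate_trust_game(
      population_config(n_participants = 24, n_conditioning_trials = 40,
                        n_test_trials = 1), seed = 1000 + s)$trials
    choice_trend(trials)$p_two_sided < 0.05
  }, TRUE)
  expect_gte(mean(!hits), 0.9)
})

test_that("behavior_report bundles the headline statistics", {
  trials <- simulate_trust_game(paper_like_config(n_participants = 8),
                                seed = 5)$trials
  rep <- behavior_report(trials)
  expect_named(rep, c("choices", "choices_by_trial", "choice_trend",
                      "summaries", "group_means", "tests"))
  expect_equal(nrow(rep$tests), 5)
  dvc <- rep$tests[rep$tests$contrast == "test mean: doctor vs control", ]
  expect_equal(dvc$df, 7)   # participants - 1
})
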