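# The synthetic cohort generator.

test_that("participant_coop_prob follows the logistic closed form", {
  zero <- cohort_config(b0 = 0, b_strat = 0, b_emo_g = 0, b_emo_e = 0,
                        b_recip = 0, b_expect = 0, b_first = 0, b_last = 0,
                        sigma_u = 0)
  for (strat in c("extortion", "generosity")) {
    for (emo in orientation_levels()) {
      expect_equal(participant_coop_prob(strat, emo, 5, 1, 0, zero), 0.5)
    }
  }
  cfg <- cohort_config(b0 = 0, b_strat = 0, b_emo_g = 0, b_emo_e = 0,
                       b_recip = 0, b_expect = 0, b_first = 1, b_last = 0,
                       sigma_u = 0)
  expect_equal(participant_coop_prob("extortion", "cooperative", 1, 0, 0, cfg),
               plogis(1))
  # emotion carries no weight under extortion by default (b_emo_e = 0)
  d <- cohort_config()
  expect_equal(
    participant_coop_prob("extortion", "cooperative", 5, 1, 0.3, d),
    participant_coop_prob("extortion", "competitive", 5, 1, 0.3, d))
})

test_that("mediator generators honor their closed forms and bounds", {
  flat <- cohort_config(a0 = 0, a_exp = 0, a_emo = 0, exp_noise_sd = 0,
                        exp_between_sd = 0)
  med <- generate_mediators(runif(10), "competitive", rep(5, 10), flat)
  expect_true(all(med$expectation == 0))
  full <- cohort_config(a0 = 0, a_exp = 100, a_emo = 0, exp_noise_sd = 0,
                        exp_between_sd = 0)
  med2 <- generate_mediators(rep(1, 5), "competitive", rep(5, 5), full)
  expect_true(all(med2$expectation == 100)) # clipped at the top
  med3 <- generate_mediators(rep(0.5, 2000), "cooperative",
                             sample(c(7, 5, 3, 2), 2000, TRUE),
                             cohort_config(seed = 1))
  expect_true(all(med3$expectation >= 0 & med3$expectation <= 100))
  expect_true(all(med3$self_report %in% self_report_levels()))
})

test_that("self-reported joy increases with the round payoff", {
  set.seed(42)
  cfg <- cohort_config()
  joy_rate <- sapply(c(2, 3, 5, 7), function(pay) {
    mean(generate_mediators(0.5, "cooperative", rep(pay, 4000),
                            cfg)$self_report == "joy")
  })
  expect_true(all(diff(joy_rate) > 0))
})

test_that("generated cohorts have the configured shape and are reproducible", {
  cfg <- cohort_config(n_per_cell = 6, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$trials), 4 * 6 * 20)
  expect_equal(nrow(a$post_task), 24)
  expect_equal(sort(unique(a$trials$strategy)), c("extortion", "generosity"))
  expect_setequal(unique(a$trials$emotion), orientation_levels())
  expect_true(all(table(a$trials$participant_id) == 20))
  expect_silent(validate_trial_table(a$trials))
  # post-task scales respect their 1..7 bounds
  expect_true(all(a$post_task$mental_demand %in% 1:7))
  expect_true(all(a$post_task$genuineness %in% 1:7))
})

test_that("counterpart play follows the cell strategy and display policy exactly", {
  co <- generate_cohort(cohort_config(n_per_cell = 150, seed = 21))
  tr <- co$trials
  # round 1: extortion defects, generosity cooperates
  r1 <- tr[tr$round == 1, ]
  expect_true(all(r1$counterpart_move[r1$strategy == "extortion"] == "D"))
  expect_true(all(r1$counterpart_move[r1$strategy == "generosity"] == "C"))
  # expressions match the orientation applied to the counterpart-view outcome
  expect_identical(tr$counterpart_expression,
                   ifelse(tr$emotion == "cooperative",
                          express("cooperative", swap_perspective(tr$outcome)),
                          express("competitive", swap_perspective(tr$outcome))))
  # conditional cooperation frequencies approach the strategy vectors
  for (strat in c("extortion", "generosity")) {
    q <- condition_strategy(strat)
    d <- tr[tr$strategy == strat, ]
    d <- d[order(d$participant_id, d$round), ]
    prev <- d$round < 20
    nxt <- d$round > 1
    prev_out <- swap_perspective(d$outcome[prev]) # counterpart view
    next_move <- d$counterpart_move[nxt]
    for (oc in outcome_levels()) {
      n_ev <- sum(prev_out == oc)
      if (n_ev < 1000) next
      phat <- mean(next_move[prev_out == oc] == "C")
      p_true <- unname(q$p[oc])
      half <- qnorm(0.995) * sqrt(p_true * (1 - p_true) / n_ev)
      expect_lt(abs(phat - p_true), half + 2e-3)
    }
  }
})

test_that("default cohorts reproduce the qualitative effect pattern", {
  means <- sapply(1:5, function(s) {
    ps <- participant_summaries(generate_cohort(
      cohort_config(n_per_cell = 60, seed = 300 + s))$trials)
    tapply(ps$coop_rate, interaction(ps$strategy, ps$emotion), mean)
  })
  m <- rowMeans(means)
  gen <- mean(m[grep("generosity", names(m))])
  ext <- mean(m[grep("extortion", names(m))])
  expect_gt(gen, ext) # strategy main effect direction
  expect_equal(names(which.max(m)), "generosity.cooperative")
  # expectations are higher under generosity (mediator direction)
  ps <- participant_summaries(generate_cohort(
    cohort_config(n_per_cell = 60, seed = 77))$trials)
  expect_gt(mean(ps$expectation[ps$strategy == "generosity"]),
            mean(ps$expectation[ps$strategy == "extortion"]))
})

test_that("the default config is calibrated to a strategy partial eta^2 near 0.2", {
  etas <- sapply(1:20, function(s) {
    ps <- participant_summaries(generate_cohort(cohort_config(seed = s))$trials)
    a <- anova_two_way(ps$coop_rate, ps$strategy, ps$emotion)
    a$table$partial_eta_sq[a$table$effect == "A"]
  })
  expect_lt(abs(mean(etas) - 0.2), 0.08)
})

test_that("cohort configs validate and round-trip through YAML", {
  expect_error(cohort_config(n_per_cell = 1), "at least 2")
  expect_error(cohort_config(sigma_u = -1), "non-negative")
  expect_error(cohort_config(b_strat = NA), "finite")
  cfg <- cohort_config(n_per_cell = 7, b_strat = 0.11, seed = 5)
  path <- withr::local_tempfile(fileext = ".yml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})
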