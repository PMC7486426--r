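# Synthetic participant cohorts.
#
# The generator produces trial tables with the structure the statistical
# pipeline assumes: a 2 (strategy: extortion/generosity) x 2 (emotion
# orientation: cooperative/competitive) between-participants design, 20
# rounds per participant, counterpart behavior driven exactly by the cell's
# zero-determinant strategy and its emotion display policy, and participant
# behavior from a logistic memory-one choice model with covariates.

#' Configuration of the synthetic cohort generator
#'
#' The participant's round-level cooperation probability is the logistic of
#' a linear predictor on the log-odds scale:
#' `b0 + b_strat [generosity] + b_emo_g [generosity & cooperative display] +
#' b_emo_e [extortion & cooperative display] + b_recip [counterpart
#' cooperated last round] + b_first [round 1] + b_last [last round] + u`,
#' with a participant random intercept `u ~ N(0, sigma_u^2)`.
#' The defaults encode the structure of the behavioral findings the pipeline
#' is designed to detect: a strategy effect much larger than the emotion
#' effect, an emotion effect present only under generosity
#' (`b_emo_e = 0`), high first-round cooperation with an end-game drop, and
#' positive reciprocity.
#'
#' Mediators: after each round the expectation rating (0-100 scale) is a
#' clipped linear function of the counterpart's cooperation frequency so far
#' and of the display orientation,
#' `clip(a_exp * frac + a_emo * [cooperative display] + N(0, exp_noise_sd), 0, 100)`,
#' and the self-reported emotion is drawn from a softmax over
#' `joy, sadness, anger, regret, neutral` whose joy log-odds increase with
#' the participant's own round payoff (temperature `emotion_temperature`).
#'
#' @param n_per_cell Participants per design cell (default 85, the study's
#'   recruitment target per condition).
#' @param n_rounds Rounds per participant (default 20).
#' @param b0 Baseline log-odds of cooperating.
#' @param b_strat Strategy effect (generosity vs extortion), log-odds.
#' @param b_emo_g Cooperative-display effect within generosity, log-odds.
#' @param b_emo_e Cooperative-display effect within extortion, log-odds
#'   (default 0: emotion carries no weight against an extortionist).
#' @param b_recip Reciprocity: boost when the counterpart cooperated in the
#'   previous round.
#' @param b_expect Expectation link: log-odds shift per 50 rating points of
#'   the expectation reported after the previous round, centered at 50
#'   (0 in round 1). This is the causal path the mediation analyses probe:
#'   participants who expect cooperation cooperate more.
#' @param b_first First-round boost.
#' @param b_last Last-round (end-game) drop; usually negative.
#' @param sigma_u SD of the participant random intercept.
#' @param a0 Expectation intercept (rating points, default 0).
#' @param a_exp Expectation loading on the counterpart's running cooperation
#'   frequency (rating points per unit frequency).
#' @param a_emo Expectation loading on a cooperative display orientation
#'   (rating points).
#' @param exp_noise_sd SD of the round-level Gaussian expectation noise
#'   (rating points).
#' @param exp_between_sd SD of a stable participant-level expectation bias
#'   (rating points): some raters are persistently more optimistic than
#'   others, independent of what the counterpart does.
#' @param emotion_temperature Softmax temperature of the self-report model;
#'   larger values flatten the distribution.
#' @param post_task Named list of latent 1-7 cell means and SD for the two
#'   post-task questions (mental demand and display genuineness).
#' @param seed Integer seed for [generate_cohort()].
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_per_cell = 85,
                          n_rounds = 20,
                          b0 = -0.9,
                          b_strat = 0.35,
                          b_emo_g = 0.5,
                          b_emo_e = 0,
                          b_recip = 0.7,
                          b_expect = 0.5,
                          b_first = 1.6,
                          b_last = -0.9,
                          sigma_u = 1.0,
                          a0 = 0,
                          a_exp = 60,
                          a_emo = 8,
                          exp_noise_sd = 16,
                          exp_between_sd = 8,
                          emotion_temperature = 1.5,
                          post_task = NULL,
                          seed = 1L) {
  if (is.null(post_task)) {
    post_task <- list(
      demand_mean = c(extortion = 3.05, generosity = 3.50),
      genuineness_mean = c(
        extortion.cooperative = 3.6, extortion.competitive = 4.4,
        generosity.cooperative = 5.5, generosity.competitive = 4.4
      ),
      sd = 1.6
    )
  }
  cfg <- list(
    schema_version = 1L,
    n_per_cell = as.integer(n_per_cell), n_rounds = as.integer(n_rounds),
    b0 = b0, b_strat = b_strat, b_emo_g = b_emo_g, b_emo_e = b_emo_e,
    b_recip = b_recip, b_expect = b_expect, b_first = b_first, b_last = b_last,
    sigma_u = sigma_u,
    a0 = a0, a_exp = a_exp, a_emo = a_emo, exp_noise_sd = exp_noise_sd,
    exp_between_sd = exp_between_sd,
    emotion_temperature = emotion_temperature,
    post_task = post_task, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  coefs <- c(cfg$b0, cfg$b_strat, cfg$b_emo_g, cfg$b_emo_e, cfg$b_recip,
             cfg$b_expect, cfg$b_first, cfg$b_last, cfg$a0, cfg$a_exp,
             cfg$a_emo)
  if (any(!is.finite(coefs))) {
    stop("cohort config: all effect coefficients must be finite",
         call. = FALSE)
  }
  if (is.na(cfg$n_per_cell) || cfg$n_per_cell < 2) {
    stop("cohort config: n_per_cell must be at least 2", call. = FALSE)
  }
  if (cfg$n_rounds < 1) {
    stop("cohort config: n_rounds must be at least 1", call. = FALSE)
  }
  if (cfg$sigma_u < 0 || cfg$exp_noise_sd < 0 || cfg$exp_between_sd < 0) {
    stop("cohort config: standard deviations must be non-negative",
         call. = FALSE)
  }
  if (cfg$emotion_temperature <= 0) {
    stop("cohort config: emotion_temperature must be positive",
         call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:",
      4 * x$n_per_cell, "participants (", x$n_per_cell, "per cell ),",
      x$n_rounds, "rounds, seed", x$seed, "\n")
  cat(sprintf(
    "  choice model: b0=%.2f strat=%.2f emoG=%.2f emoE=%.2f recip=%.2f first=%.2f last=%.2f sigma_u=%.2f\n",
    x$b0, x$b_strat, x$b_emo_g, x$b_emo_e, x$b_recip, x$b_first, x$b_last,
    x$sigma_u))
  invisible(x)
}

#' Round-level cooperation probability of a synthetic participant
#'
#' Logistic choice model of the generator; vectorized over participants.
#'
#' @param strategy `"extortion"` or `"generosity"` (recycled).
#' @param emotion `"cooperative"` or `"competitive"` display orientation.
#' @param round Round number, `1..n_rounds`.
#' @param prev_counterpart_coop Logical/0-1: the counterpart cooperated in
#'   the previous round (0 in round 1).
#' @param prev_expectation Expectation rating reported after the previous
#'   round (0-100; the neutral default 50 contributes nothing and is used
#'   in round 1).
#' @param u Participant random intercept(s).
#' @param config A [cohort_config()].
#' @return Cooperation probabilities in `(0, 1)`.
#' @export
participant_coop_prob <- function(strategy, emotion, round,
                                  prev_counterpart_coop, u,
                                  config = cohort_config(),
                                  prev_expectation = 50) {
  gen <- as.numeric(strategy == "generosity")
  coop_disp <- as.numeric(emotion == "cooperative")
  lp <- config$b0 +
    config$b_strat * gen +
    config$b_emo_g * gen * coop_disp +
    config$b_emo_e * (1 - gen) * coop_disp +
    config$b_recip * as.numeric(prev_counterpart_coop) +
    config$b_expect * (prev_expectation - 50) / 50 +
    config$b_first * as.numeric(round == 1L) +
    config$b_last * as.numeric(round == config$n_rounds) +
    u
  stats::plogis(lp)
}

#' Generate round-level mediator measures
#'
#' Vectorized over participants. The expectation rating is
#' `clip(a_exp * counterpart_coop_frac + a_emo * [cooperative orientation] +
#' noise, 0, 100)`; the self-report is a draw from a softmax whose joy
#' log-odds grow with the round payoff (relative to the mutual-defection
#' payoff), with mild sadness/anger weight on low payoffs and a small regret
#' weight after exploiting the counterpart.
#'
#' @param counterpart_coop_frac Counterpart cooperation frequency over the
#'   rounds played so far, in `[0, 1]`.
#' @param orientation Display orientation(s), recycled.
#' @param round_payoff The participant's payoff this round, in points.
#' @param config A [cohort_config()].
#' @param m A [payoff_matrix()].
#' @param rater_bias Optional per-participant expectation bias (rating
#'   points), drawn once per participant by [generate_cohort()] with SD
#'   `exp_between_sd`.
#' @return List with numeric `expectation` (0-100) and character
#'   `self_report`.
#' @export
generate_mediators <- function(counterpart_coop_frac, orientation,
                               round_payoff, config = cohort_config(),
                               m = payoff_matrix(), rater_bias = 0) {
  n <- max(length(counterpart_coop_frac), length(round_payoff))
  coop_disp <- as.numeric(rep_len(orientation, n) == "cooperative")
  expectation <- config$a0 +
    config$a_exp * rep_len(counterpart_coop_frac, n) +
    config$a_emo * coop_disp + rep_len(rater_bias, n)
  if (config$exp_noise_sd > 0) {
    expectation <- expectation + stats::rnorm(n, 0, config$exp_noise_sd)
  }
  expectation <- pmin(pmax(expectation, 0), 100)

  pay <- rep_len(round_payoff, n)
  tau <- config$emotion_temperature
  logits <- cbind(
    joy     = (pay - m[["P"]]) / tau,
    sadness = (m[["P"]] - pay) / (2 * tau),
    anger   = (m[["P"]] - pay) / (2 * tau) + (pay == m[["S"]]) / tau,
    regret  = (pay == m[["T"]]) * 0.5 / tau - 1,
    neutral = 0
  )
  pr <- exp(logits - apply(logits, 1, max))
  pr <- pr / rowSums(pr)
  u <- stats::runif(n)
  cum <- t(apply(pr, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  list(expectation = expectation,
       self_report = self_report_levels()[idx])
}

#' Generate a synthetic cohort
#'
#' Simulates all four design cells. Counterpart moves follow the cell's
#' zero-determinant strategy exactly (initial move included) and counterpart
#' expressions follow [express()] for the cell's orientation; participant
#' moves follow [participant_coop_prob()]; mediators follow
#' [generate_mediators()]. The same config (seed included) always yields
#' byte-identical tables.
#'
#' @param config A [cohort_config()].
#' @param m A [payoff_matrix()].
#' @return List with two data frames: `trials` (one row per participant and
#'   round, schema of [read_trial_table()]) and `post_task`
#'   (`participant_id`, `mental_demand`, `genuineness`, both integer 1-7).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_cell = 5, seed = 42))
#' head(cohort$trials)
#' @export
generate_cohort <- function(config = cohort_config(), m = payoff_matrix()) {
  config <- validate_cohort_config(config)
  k <- config$n_rounds
  n <- config$n_per_cell
  cells <- expand.grid(strategy = c("extortion", "generosity"),
                       emotion = c("cooperative", "competitive"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  with_rng_seed(config$seed, {
    trial_blocks <- vector("list", nrow(cells))
    post_blocks <- vector("list", nrow(cells))
    pid_offset <- 0L
    for (ci in seq_len(nrow(cells))) {
      strat_name <- cells$strategy[ci]
      emo_name <- cells$emotion[ci]
      q <- condition_strategy(strat_name)
      ids <- sprintf("p%04d", pid_offset + seq_len(n))
      pid_offset <- pid_offset + n

      u <- stats::rnorm(n, 0, config$sigma_u)
      rater_bias <- stats::rnorm(n, 0, config$exp_between_sd)
      pm <- cm <- matrix("", n, k)
      expr <- sr <- matrix("", n, k)
      expec <- matrix(0, n, k)
      cm_coop_count <- numeric(n)
      prev_cm_coop <- numeric(n)
      prev_expec <- rep(50, n)
      prev_outcome_cp <- rep(NA_character_, n) # counterpart perspective
      for (t in seq_len(k)) {
        pr_p <- participant_coop_prob(strat_name, emo_name, t,
                                      prev_cm_coop, u, config, prev_expec)
        # counterpart: initial move in round 1, memory-one afterwards
        pr_c <- if (t == 1L) rep(as.numeric(q$initial == "C"), n)
                else unname(q$p[prev_outcome_cp])
        p_move <- ifelse(stats::runif(n) < pr_p, "C", "D")
        c_move <- ifelse(stats::runif(n) < pr_c, "C", "D")
        pm[, t] <- p_move
        cm[, t] <- c_move
        out_participant <- paste0(p_move, c_move)
        out_counterpart <- paste0(c_move, p_move)
        prev_outcome_cp <- out_counterpart
        prev_cm_coop <- as.numeric(c_move == "C")
        cm_coop_count <- cm_coop_count + prev_cm_coop
        expr[, t] <- express(emo_name, out_counterpart)
        med <- generate_mediators(cm_coop_count / t, emo_name,
                                  payoffs_of(out_participant, m)$focal,
                                  config, m, rater_bias)
        expec[, t] <- med$expectation
        prev_expec <- med$expectation
        sr[, t] <- med$self_report
      }
      trial_blocks[[ci]] <- data.frame(
        participant_id = rep(ids, each = k),
        strategy = strat_name, emotion = emo_name,
        round = rep(seq_len(k), times = n),
        participant_move = as.vector(t(pm)),
        counterpart_move = as.vector(t(cm)),
        outcome = paste0(as.vector(t(pm)), as.vector(t(cm))),
        counterpart_expression = as.vector(t(expr)),
        self_report = as.vector(t(sr)),
        expectation_rating = round(as.vector(t(expec)), 3),
        stringsAsFactors = FALSE
      )
      pt <- config$post_task
      demand <- stats::rnorm(n, pt$demand_mean[[strat_name]], pt$sd)
      genu <- stats::rnorm(
        n, pt$genuineness_mean[[paste(strat_name, emo_name, sep = ".")]],
        pt$sd)
      post_blocks[[ci]] <- data.frame(
        participant_id = ids,
        strategy = strat_name, emotion = emo_name,
        mental_demand = pmin(pmax(round(demand), 1), 7),
        genuineness = pmin(pmax(round(genu), 1), 7),
        stringsAsFactors = FALSE
      )
    }
    list(trials = do.call(rbind, trial_blocks),
         post_task = do.call(rbind, post_blocks))
  })
}

#' Read or write a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `read_cohort_config()` returns a validated [cohort_config()];
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  # named vectors must go out as YAML maps, not bare sequences
  out$post_task$demand_mean <- as.list(out$post_task$demand_mean)
  out$post_task$genuineness_mean <- as.list(out$post_task$genuineness_mean)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1L) {
    stop("unsupported cohort config schema version", call. = FALSE)
  }
  raw$post_task$demand_mean <- unlist(raw$post_task$demand_mean)
  raw$post_task$genuineness_mean <- unlist(raw$post_task$genuineness_mean)
  validate_cohort_config(raw)
}
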