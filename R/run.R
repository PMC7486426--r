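# End-to-end orchestration: simulate a cohort (or take a trial table) and
# run every analysis of the statistical pipeline.

#' Run the full analysis pipeline on a trial table
#'
#' Computes all five analysis blocks the study design calls for:
#' strategy x emotion Type III ANOVAs on cooperation rate, joy self-report
#' proportion and mean expectation rating; the planned synergistic contrast
#' on cooperation rate; emotion t tests split by strategy; the
#' round x strategy x emotion mixed ANOVA with Huynh-Feldt correction; and
#' multiple mediation of the strategy and emotion effects through the
#' expectation rating and the four emotion self-report proportions.
#'
#' @param trials A trial table (schema of [read_trial_table()]).
#' @param post_task Optional post-task data frame (adds ANOVAs on mental
#'   demand and genuineness).
#' @param n_boot Bootstrap resamples for the mediation models.
#' @param seed Seed for the mediation bootstrap.
#' @param contrast_weights Planned-contrast weights over the cells in
#'   `sort(unique(interaction(strategy, emotion)))` order; the default puts
#'   `+3` on generosity x cooperative and `-1` elsewhere.
#' @return Named list of result objects (classes `anova_table`,
#'   `contrast_result`, `mixed_anova_table`, `mediation_result`).
#' @export
analyze_trials <- function(trials, post_task = NULL, n_boot = 5000,
                           seed = 1L, contrast_weights = NULL) {
  validate_trial_table(trials)
  ps <- participant_summaries(trials)
  cell <- interaction(ps$strategy, ps$emotion, drop = TRUE)
  if (is.null(contrast_weights)) {
    contrast_weights <- ifelse(levels(cell) == "generosity.cooperative",
                               3, -1)
  }
  res <- list()
  res$anova <- list(
    cooperation = anova_two_way(ps$coop_rate, ps$strategy, ps$emotion,
                                names = c("strategy", "emotion")),
    joy = anova_two_way(ps$joy, ps$strategy, ps$emotion,
                        names = c("strategy", "emotion")),
    expectation = anova_two_way(ps$expectation, ps$strategy, ps$emotion,
                                names = c("strategy", "emotion"))
  )
  if (!is.null(post_task)) {
    res$anova$mental_demand <- anova_two_way(
      post_task$mental_demand, post_task$strategy, post_task$emotion,
      names = c("strategy", "emotion"))
    res$anova$genuineness <- anova_two_way(
      post_task$genuineness, post_task$strategy, post_task$emotion,
      names = c("strategy", "emotion"))
  }
  res$contrast <- planned_contrast(ps$coop_rate, cell,
                                   weights = contrast_weights)
  gen <- ps[ps$strategy == "generosity", ]
  ext <- ps[ps$strategy == "extortion", ]
  res$t_tests <- list(
    emotion_within_generosity = ttest_ind(
      gen$coop_rate[gen$emotion == "cooperative"],
      gen$coop_rate[gen$emotion == "competitive"]),
    emotion_within_extortion = ttest_ind(
      ext$coop_rate[ext$emotion == "cooperative"],
      ext$coop_rate[ext$emotion == "competitive"])
  )
  res$mixed_anova <- mixed_anova(trials)
  mediators <- c("expectation", "joy", "sadness", "regret", "anger")
  res$mediation <- list(
    strategy = multiple_mediation(ps, iv = "strategy",
                                  mediators = mediators, dv = "coop_rate",
                                  n_boot = n_boot, seed = seed,
                                  code_one = "generosity"),
    emotion = multiple_mediation(ps, iv = "emotion",
                                 mediators = mediators, dv = "coop_rate",
                                 n_boot = n_boot, seed = seed,
                                 code_one = "cooperative")
  )
  res
}

results_to_list <- function(res) {
  unpack <- function(x) {
    if (inherits(x, "anova_table")) {
      list(table = x$table, mse = x$mse, df_error = x$df_error,
           cell_means = as.list(x$cell_means),
           pairwise = x$pairwise)
    } else if (inherits(x, "contrast_result")) {
      x[c("estimate", "se", "t", "df", "p")]
    } else if (inherits(x, "mixed_anova_table")) {
      list(table = x$table, gg_epsilon = x$gg_epsilon,
           hf_epsilon = x$hf_epsilon)
    } else if (inherits(x, "mediation_result")) {
      list(effects = x$effects, n_boot = x$n_boot, seed = x$seed,
           coding = x$coding)
    } else if (is.list(x)) {
      lapply(x, unpack)
    } else x
  }
  lapply(res, unpack)
}

#' Simulate a cohort and write the full report bundle
#'
#' Generates a synthetic cohort from `config`, runs [analyze_trials()], and
#' writes to `out_dir`: the trial and post-task tables (CSV), all analysis
#' results (`results.json`), and a run manifest (`manifest.json`: package
#' version, seeds, config echo and config file hash) sufficient to reproduce
#' the run. Outputs are byte-identical across runs with the same config.
#'
#' @param config A [cohort_config()]; its `seed` drives both the simulation
#'   and the mediation bootstrap.
#' @param out_dir Output directory (created if needed).
#' @param n_boot Bootstrap resamples for the mediation models.
#' @param quiet Suppress stage messages.
#' @return The list of results from [analyze_trials()], invisibly.
#' @export
run_experiment <- function(config = cohort_config(), out_dir, n_boot = 5000,
                           quiet = FALSE) {
  config <- validate_cohort_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[coopsignal] ", ...)

  say("simulating cohort (seed ", config$seed, ", ",
      4 * config$n_per_cell, " participants)")
  cohort <- generate_cohort(config)
  write_trial_table(cohort$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(cohort$post_task, file.path(out_dir, "post_task.csv"),
                   row.names = FALSE, quote = FALSE)

  say("running analyses (", n_boot, " bootstrap resamples)")
  res <- analyze_trials(cohort$trials, cohort$post_task,
                        n_boot = n_boot, seed = config$seed)
  jsonlite::write_json(results_to_list(res),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_path <- file.path(out_dir, "config.yml")
  write_cohort_config(config, cfg_path)
  manifest <- list(
    package = "coopsignal",
    version = as.character(utils::packageVersion("coopsignal")),
    seed = config$seed, n_boot = n_boot,
    config_file = "config.yml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = c("trials.csv", "post_task.csv", "results.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("report bundle written to ", out_dir)
  invisible(res)
}
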