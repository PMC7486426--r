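# Trial-table CSV reading/writing with schema validation.

trial_table_columns <- function() {
  c("participant_id", "strategy", "emotion", "round", "participant_move",
    "counterpart_move", "outcome", "counterpart_expression", "self_report",
    "expectation_rating")
}

validate_trial_table <- function(df) {
  missing_cols <- setdiff(trial_table_columns(), colnames(df))
  if (length(missing_cols)) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("trial table has no rows", call. = FALSE)
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("trial table row %d: %s", which(!ok)[1], what),
           call. = FALSE)
    }
  }
  bad_row(df$strategy %in% c("extortion", "generosity"),
          "invalid strategy value")
  bad_row(df$emotion %in% orientation_levels(), "invalid emotion value")
  bad_row(df$participant_move %in% move_levels(),
          "invalid participant_move")
  bad_row(df$counterpart_move %in% move_levels(), "invalid counterpart_move")
  bad_row(df$outcome %in% outcome_levels(), "invalid outcome code")
  bad_row(df$counterpart_expression %in% expression_levels(),
          "invalid counterpart_expression")
  bad_row(df$self_report %in% self_report_levels(), "invalid self_report")
  bad_row(is.finite(df$round) & df$round >= 1, "invalid round number")
  bad_row(is.finite(df$expectation_rating) &
            df$expectation_rating >= 0 & df$expectation_rating <= 100,
          "expectation_rating outside [0, 100]")
  bad_row(df$outcome == paste0(df$participant_move, df$counterpart_move),
          "outcome inconsistent with the two moves")
  invisible(df)
}

#' Read or write a trial table CSV
#'
#' The trial table is the package's central tabular format: one row per
#' participant and round, with columns `participant_id`, `strategy`
#' (`extortion`/`generosity`), `emotion` (`cooperative`/`competitive`),
#' `round`, `participant_move`, `counterpart_move` (`C`/`D`), `outcome`
#' (participant's move first), `counterpart_expression`, `self_report`, and
#' `expectation_rating` (0-100). Reading validates every enum, the round
#' range, the `[0, 100]` rating range, and that each `outcome` matches the
#' two move columns; violations report the first offending row.
#'
#' @param path CSV file path (RFC-4180, UTF-8, header required).
#' @param trials A trial table data frame.
#' @return `read_trial_table()` returns the validated data frame;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse trial table: ",
                             conditionMessage(e), call. = FALSE)
  )
  validate_trial_table(df)
  df
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  utils::write.csv(trials[, trial_table_columns()], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
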