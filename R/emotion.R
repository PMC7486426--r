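# Outcome-contingent emotion display policies of the counterpart.
#
# Outcomes here are encoded from the counterpart strategist's perspective:
# "DC" means the strategist defected while the participant cooperated, i.e.
# the strategist exploited the participant.

#' Emotion display orientations and expression vocabulary
#'
#' The counterpart displays one of four expressions (`joy`, `regret`,
#' `anger`, `neutral`) after each round, under one of two orientations.
#' Participants' own self-reports use a five-way vocabulary that adds
#' `sadness`.
#'
#' @return Character vector of the valid values.
#' @export
orientation_levels <- function() c("cooperative", "competitive")

#' @rdname orientation_levels
#' @export
expression_levels <- function() c("joy", "regret", "anger", "neutral")

#' @rdname orientation_levels
#' @export
self_report_levels <- function() {
  c("joy", "sadness", "anger", "regret", "neutral")
}

#' Full outcome-to-expression table of an orientation
#'
#' The cooperative orientation signals joy after mutual cooperation and
#' regret after exploiting the participant; the competitive orientation
#' reverses exactly those two cells (regret after mutual cooperation, joy
#' after exploitation). Both show anger after being exploited and neutral
#' after mutual defection, so the two orientations are distinguishable only
#' after `CC` or `DC` outcomes.
#'
#' @param orientation `"cooperative"` or `"competitive"`.
#' @return Named character vector mapping each outcome (strategist
#'   perspective) to an expression.
#' @examples
#' expression_table("cooperative")
#' @export
expression_table <- function(orientation = orientation_levels()) {
  orientation <- match.arg(orientation)
  switch(orientation,
    cooperative = c(CC = "joy", CD = "anger", DC = "regret", DD = "neutral"),
    competitive = c(CC = "regret", CD = "anger", DC = "joy", DD = "neutral")
  )
}

#' Expression displayed after a round outcome
#'
#' @inheritParams expression_table
#' @param outcome Outcome code(s) from the counterpart strategist's
#'   perspective (first letter = strategist's move); vectorized.
#' @return Expression(s), one of [expression_levels()].
#' @examples
#' express("competitive", "DC") # joy after exploiting the participant
#' @export
express <- function(orientation, outcome) {
  check_outcomes(outcome)
  unname(expression_table(orientation)[outcome])
}
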