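# Stage game: payoff matrix, moves and round outcomes.

#' Outcome ordering used throughout the package
#'
#' Every 4-vector indexed by the previous round's outcome (strategy
#' probabilities, stationary distributions, payoff vectors) uses the fixed
#' order `CC, CD, DC, DD`, where the first letter is the focal player's move
#' and the second the co-player's.
#'
#' @return Character vector `c("CC", "CD", "DC", "DD")`.
#' @export
outcome_levels <- function() c("CC", "CD", "DC", "DD")

#' Moves of the stage game
#'
#' @return Character vector `c("C", "D")` (cooperate, defect).
#' @export
move_levels <- function() c("C", "D")

#' Prisoner's dilemma payoff matrix
#'
#' Constructs the four stage-game payoffs of a prisoner's dilemma. The
#' defaults are the payoffs used in the behavioral task this package models:
#' temptation 7, reward 5, punishment 3, sucker 2.
#'
#' @param T Temptation payoff (defect against a cooperator).
#' @param R Reward for mutual cooperation.
#' @param P Punishment for mutual defection.
#' @param S Sucker payoff (cooperate against a defector).
#'
#' @return An object of class `payoff_matrix`: a named numeric vector with
#'   elements `T`, `R`, `P`, `S` satisfying `T > R > P > S`.
#' @examples
#' m <- payoff_matrix()
#' payoffs_of("DC", m) # focal defected against a cooperator: 7 vs 2
#' @export
payoff_matrix <- function(T = 7, R = 5, P = 3, S = 2) {
  m <- c(T = as.numeric(T), R = as.numeric(R), P = as.numeric(P),
         S = as.numeric(S))
  if (any(!is.finite(m))) {
    stop("payoff matrix entries must be finite", call. = FALSE)
  }
  if (!(m["T"] > m["R"] && m["R"] > m["P"] && m["P"] > m["S"])) {
    stop("payoff matrix must satisfy T > R > P > S", call. = FALSE)
  }
  structure(m, class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Prisoner's dilemma payoffs: T =", x[["T"]], "> R =", x[["R"]],
      "> P =", x[["P"]], "> S =", x[["S"]], "\n")
  invisible(x)
}

#' Per-outcome payoff vectors for the focal player and the co-player
#'
#' In the canonical outcome order (`CC, CD, DC, DD`) the focal player earns
#' `(R, S, T, P)` and the co-player `(R, T, S, P)`.
#'
#' @param m A [payoff_matrix()].
#' @return List with numeric 4-vectors `focal` and `other`, named by outcome.
#' @export
payoff_vectors <- function(m = payoff_matrix()) {
  stopifnot(inherits(m, "payoff_matrix"))
  list(
    focal = stats::setNames(c(m[["R"]], m[["S"]], m[["T"]], m[["P"]]),
                            outcome_levels()),
    other = stats::setNames(c(m[["R"]], m[["T"]], m[["S"]], m[["P"]]),
                            outcome_levels())
  )
}

check_moves <- function(x, arg) {
  if (!all(x %in% move_levels())) {
    stop(sprintf("'%s' must be one of \"C\", \"D\"", arg), call. = FALSE)
  }
  x
}

#' Encode a round outcome from two moves
#'
#' @param focal,other Moves (`"C"` or `"D"`); vectors are paired elementwise.
#' @return Outcome code(s), focal player's move first (e.g. `(D, C)` is
#'   `"DC"`).
#' @examples
#' outcome_of("D", "C")
#' @export
outcome_of <- function(focal, other) {
  check_moves(focal, "focal")
  check_moves(other, "other")
  paste0(focal, other)
}

#' Swap the perspective of an outcome code
#'
#' `CD` seen by the focal player is `DC` seen by the co-player; `CC` and `DD`
#' are symmetric.
#'
#' @param outcome Outcome code(s) in `CC, CD, DC, DD`.
#' @return Outcome code(s) from the co-player's perspective.
#' @export
swap_perspective <- function(outcome) {
  map <- c(CC = "CC", CD = "DC", DC = "CD", DD = "DD")
  check_outcomes(outcome)
  unname(map[outcome])
}

check_outcomes <- function(x) {
  if (!all(x %in% outcome_levels())) {
    stop("outcome must be one of \"CC\", \"CD\", \"DC\", \"DD\"",
         call. = FALSE)
  }
  x
}

#' Points earned in a round
#'
#' @param outcome Outcome code(s), focal player's move first.
#' @param m A [payoff_matrix()].
#' @return List with numeric vectors `focal` and `other`.
#' @examples
#' payoffs_of("CC", payoff_matrix()) # both earn R = 5
#' @export
payoffs_of <- function(outcome, m = payoff_matrix()) {
  check_outcomes(outcome)
  v <- payoff_vectors(m)
  list(focal = unname(v$focal[outcome]), other = unname(v$other[outcome]))
}
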