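# Iterated-match engine for two players.

with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Normalize an opponent specification into a policy closure
#   f(round, prev_outcome_own_perspective) -> probability of cooperating.
# Accepted forms: a memory_one_strategy; a single move "C"/"D" (fixed);
# a character vector of moves (scripted, recycled); or a function with the
# closure signature returning a probability.
as_policy <- function(opponent, n_rounds) {
  if (is_memory_one(opponent)) {
    if (anyNA(opponent$p)) {
      stop("strategy has an undetermined entry; complete it first",
           call. = FALSE)
    }
    return(function(round, prev_outcome) {
      if (round == 1L) as.numeric(opponent$initial == "C")
      else unname(opponent$p[prev_outcome])
    })
  }
  if (is.character(opponent)) {
    check_moves(opponent, "opponent")
    moves <- rep_len(opponent, n_rounds)
    return(function(round, prev_outcome) as.numeric(moves[round] == "C"))
  }
  if (is.function(opponent)) return(opponent)
  stop("'opponent' must be a memory_one_strategy, move(s), or a function",
       call. = FALSE)
}

#' Play an iterated prisoner's dilemma match
#'
#' Simulates `n_rounds` rounds between a focal memory-one strategy and an
#' opponent policy. Round 1 uses each player's initial move; every later
#' round conditions on the previous outcome. One seeded generator drives the
#' whole match and uniform draws are consumed in round order, focal player
#' first, so identical inputs and seed give a bitwise-identical record.
#'
#' @param p Focal player: a [memory_one_strategy()].
#' @param opponent Opponent policy: a [memory_one_strategy()], a single move
#'   (`"C"`/`"D"`, played every round), a character vector of scripted moves
#'   (recycled to `n_rounds`), or a function
#'   `f(round, prev_outcome)` returning the opponent's cooperation
#'   probability, with `prev_outcome` encoded from the opponent's own
#'   perspective.
#' @param n_rounds Number of rounds (default 20, as in the behavioral task).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @param m A [payoff_matrix()].
#'
#' @return A `match_record`: a data frame with columns `round`,
#'   `focal_move`, `other_move`, `outcome`, `focal_points`, `other_points`,
#'   and attribute `totals` (named numeric, summed points).
#' @examples
#' rec <- play_match(zd_extortion(), always_cooperate(), 20, seed = 1)
#' attr(rec, "totals")
#' @export
play_match <- function(p, opponent, n_rounds = 20, seed = NULL,
                       m = payoff_matrix()) {
  stopifnot(is_memory_one(p), n_rounds >= 1)
  if (anyNA(p$p)) {
    stop("strategy has an undetermined entry; complete it first",
         call. = FALSE)
  }
  pol <- as_policy(opponent, n_rounds)
  foc <- as_policy(p, n_rounds)

  with_rng_seed(seed, {
    focal_move <- other_move <- character(n_rounds)
    outcome <- character(n_rounds)
    prev <- NA_character_
    for (t in seq_len(n_rounds)) {
      pr_f <- foc(t, prev)
      pr_o <- pol(t, if (t > 1L) swap_perspective(prev) else NA_character_)
      focal_move[t] <- if (stats::runif(1) < pr_f) "C" else "D"
      other_move[t] <- if (stats::runif(1) < pr_o) "C" else "D"
      prev <- outcome[t] <- paste0(focal_move[t], other_move[t])
    }
    pts <- payoffs_of(outcome, m)
    rec <- data.frame(
      round = seq_len(n_rounds),
      focal_move = focal_move, other_move = other_move, outcome = outcome,
      focal_points = pts$focal, other_points = pts$other,
      stringsAsFactors = FALSE
    )
    structure(rec,
              totals = c(focal = sum(pts$focal), other = sum(pts$other)),
              class = c("match_record", "data.frame"))
  })
}

#' Write a match record as a CSV round log
#'
#' @param record A `match_record` from [play_match()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_match_record <- function(record, path) {
  stopifnot(inherits(record, "match_record"))
  utils::write.csv(as.data.frame(record), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
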