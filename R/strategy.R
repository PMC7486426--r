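# Memory-one strategies, including the two zero-determinant strategies used
# as counterparts in the behavioral task.

#' Memory-one strategy
#'
#' A memory-one strategy is specified by four cooperation probabilities
#' conditioned on the previous round's outcome (in the canonical order
#' `CC, CD, DC, DD`, from this player's own perspective) plus a first-round
#' move.
#'
#' @param p Numeric 4-vector of cooperation probabilities
#'   `(p_CC, p_CD, p_DC, p_DD)`, each in `[0, 1]` (closed interval, no
#'   tolerance slack). A single `NA` entry is allowed only when the vector is
#'   destined for [zd_complete()].
#' @param initial First-round move, `"C"` or `"D"`.
#' @param name Optional label used for printing and serialization.
#'
#' @return An object of class `memory_one_strategy`.
#' @seealso [zd_extortion()], [zd_generosity()], [make_zd()]
#' @examples
#' tit_for_tat()
#' memory_one_strategy(c(0.5, 0.5, 0.5, 0.5), initial = "C", name = "random")
#' @export
memory_one_strategy <- function(p, initial = "C", name = NULL) {
  if (length(p) != 4L || !is.numeric(p)) {
    stop("'p' must be a numeric vector of length 4", call. = FALSE)
  }
  known <- !is.na(p)
  if (any(p[known] < 0 | p[known] > 1)) {
    bad <- outcome_levels()[known & (p < 0 | p > 1)]
    stop(sprintf("cooperation probability after %s outside [0, 1]",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  check_moves(initial, "initial")
  structure(
    list(p = stats::setNames(as.numeric(p), outcome_levels()),
         initial = initial, name = name),
    class = "memory_one_strategy"
  )
}

#' @export
print.memory_one_strategy <- function(x, ...) {
  cat("Memory-one strategy", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "\n")
  cat("  p(C | CC, CD, DC, DD) =",
      paste(formatC(x$p, digits = 4, format = "fg"), collapse = ", "), "\n")
  cat("  first move:", x$initial, "\n")
  invisible(x)
}

is_memory_one <- function(x) inherits(x, "memory_one_strategy")

#' Classic deterministic strategies
#'
#' `always_cooperate()` and `always_defect()` are the two unconditional
#' strategies; `tit_for_tat()` copies the co-player's previous move and opens
#' with cooperation.
#'
#' @return A [memory_one_strategy()].
#' @export
always_cooperate <- function() {
  memory_one_strategy(c(1, 1, 1, 1), "C", name = "always-cooperate")
}

#' @rdname always_cooperate
#' @export
always_defect <- function() {
  memory_one_strategy(c(0, 0, 0, 0), "D", name = "always-defect")
}

#' @rdname always_cooperate
#' @export
tit_for_tat <- function() {
  memory_one_strategy(c(1, 0, 1, 0), "C", name = "tit-for-tat")
}

# Probabilities printed to 3 decimals in the study are stored as exact
# rationals so downstream linear-algebra identities hold exactly.
paper_rationals <- function() {
  c(0, 1, 9 / 13, 7 / 13, 4 / 13, 6 / 13, 2 / 11, 4 / 11, 9 / 11, 7 / 11)
}

snap_probability <- function(p, tol = 5e-4) {
  cand <- paper_rationals()
  out <- p
  for (i in seq_along(p)) {
    if (is.na(p[i])) next
    d <- abs(cand - p[i])
    if (min(d) <= tol) out[i] <- cand[which.min(d)]
  }
  out
}

#' Strategy constructor that snaps rounded probabilities to exact rationals
#'
#' The study reports its strategy probabilities to three decimals (0.692,
#' 0.538, 0.182, 0.364). These are decimal roundings of the exact rationals
#' 9/13, 7/13, 2/11 and 4/11. This constructor snaps any entry within
#' `5e-4` of such a rational to the exact value, so that zero-determinant
#' identities hold to machine precision.
#'
#' @inheritParams memory_one_strategy
#' @param tol Snapping tolerance (absolute).
#' @return A [memory_one_strategy()].
#' @examples
#' paper_strategy(c(0.692, 0, 0.538, 0), initial = "D")$p # exact 9/13, 7/13
#' @export
paper_strategy <- function(p, initial = "C", name = NULL, tol = 5e-4) {
  memory_one_strategy(snap_probability(p, tol), initial, name)
}

#' The extortion strategy of the behavioral task
#'
#' A zero-determinant extortion strategy for payoffs `(T, R, P, S) =
#' (7, 5, 3, 2)`: it cooperates with probability 9/13 (69.2%) after mutual
#' cooperation and 7/13 (53.8%) after exploiting the co-player, otherwise it
#' defects, and it opens with defection. It unilaterally enforces
#' `s_X - P = 3 (s_Y - P)`: the extortionist's surplus over the
#' mutual-defection payoff is three times the co-player's.
#'
#' @return A [memory_one_strategy()].
#' @export
zd_extortion <- function() {
  memory_one_strategy(c(9 / 13, 0, 7 / 13, 0), "D", name = "extortion")
}

#' The generosity strategy of the behavioral task
#'
#' A zero-determinant generous strategy for payoffs `(T, R, P, S) =
#' (7, 5, 3, 2)`: it always cooperates after the co-player cooperated, still
#' cooperates with probability 2/11 (18.2%) after being exploited and 4/11
#' (36.4%) after mutual defection, and opens with cooperation. It enforces
#' `s_X - R = 3 (s_Y - R)`: the strategist absorbs a three-fold share of any
#' shortfall below mutual cooperation.
#'
#' @return A [memory_one_strategy()].
#' @export
zd_generosity <- function() {
  memory_one_strategy(c(1, 2 / 11, 1, 4 / 11), "C", name = "generosity")
}

#' Condition strategy lookup
#'
#' @param strategy `"extortion"` or `"generosity"`.
#' @return The corresponding [memory_one_strategy()].
#' @export
condition_strategy <- function(strategy = c("extortion", "generosity")) {
  strategy <- match.arg(strategy)
  switch(strategy, extortion = zd_extortion(), generosity = zd_generosity())
}
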