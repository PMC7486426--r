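# Zero-determinant strategy algebra: construction, certification, completion,
# stationary outcome distributions and long-run payoffs.
#
# A memory-one strategy p = (p_CC, p_CD, p_DC, p_DD) is zero-determinant
# (Press & Dyson) when its adjusted vector
#   p~ = (p_CC - 1, p_CD - 1, p_DC, p_DD)
# lies in the span of the two payoff vectors and the constant:
#   p~ = alpha * S_X + beta * S_Y + gamma * 1,
# with S_X = (R, S, T, P) the strategist's payoffs and S_Y = (R, T, S, P)
# the co-player's. Such a strategy unilaterally enforces
# alpha * s_X + beta * s_Y + gamma = 0 between the long-run payoffs, i.e.
# s_X - ell = chi (s_Y - ell) with baseline ell = -gamma/(alpha+beta) and
# slope chi = -beta/alpha.

p_tilde <- function(p) p - c(1, 1, 0, 0)

#' Construct a zero-determinant strategy from (baseline, slope, scale)
#'
#' Builds the memory-one strategy whose adjusted probability vector is
#' `phi * ((S_X - ell) - chi * (S_Y - ell))`, which enforces the long-run
#' payoff relation `s_X - ell = chi (s_Y - ell)`. With baseline `ell = P`
#' this is an extortion strategy (and the first move defaults to defection);
#' with `ell = R` it is a generous strategy (first move cooperation).
#'
#' @param ell Baseline payoff of the enforced relation, in points.
#' @param chi Slope (extortion factor), dimensionless, `>= 1`.
#' @param phi Scale, dimensionless, `> 0`; must be small enough that all
#'   four probabilities land in `[0, 1]`.
#' @param m A [payoff_matrix()].
#' @param initial First-round move; by convention defection when `ell`
#'   equals the mutual-defection payoff, cooperation otherwise.
#' @param name Optional label.
#'
#' @return A [memory_one_strategy()] whose [zd_certificate()] recovers
#'   `(ell, chi)` with residual at machine precision.
#' @examples
#' make_zd(ell = 3, chi = 3, phi = 1 / 13) # the task's extortion strategy
#' make_zd(ell = 5, chi = 3, phi = 1 / 11) # the task's generosity strategy
#' @export
make_zd <- function(ell, chi, phi, m = payoff_matrix(),
                    initial = NULL, name = NULL) {
  stopifnot(chi >= 1, phi > 0)
  v <- payoff_vectors(m)
  tilde <- phi * ((v$focal - ell) - chi * (v$other - ell))
  p <- tilde + c(1, 1, 0, 0)
  bad <- p < 0 | p > 1
  if (any(bad)) {
    stop(sprintf(
      "parameters infeasible: p after %s = %s outside [0, 1]",
      paste(outcome_levels()[bad], collapse = ", "),
      paste(signif(p[bad], 4), collapse = ", ")), call. = FALSE)
  }
  if (is.null(initial)) initial <- if (ell == m[["P"]]) "D" else "C"
  memory_one_strategy(unname(p), initial, name = name)
}

#' Certify whether a memory-one strategy is zero-determinant
#'
#' Fits `p~ = alpha * S_X + beta * S_Y + gamma * 1` (four equations, three
#' unknowns) by least squares and reports the maximum absolute residual. The
#' strategy is certified ZD when the residual does not exceed `tol`. When the
#' fit is consistent, the enforced payoff relation
#' `alpha * s_X + beta * s_Y + gamma = 0` is summarized by its baseline
#' `-gamma/(alpha+beta)` (defined when `alpha + beta != 0`) and slope
#' `-beta/alpha` (defined when `alpha != 0`).
#'
#' @param p A [memory_one_strategy()] (all four entries known).
#' @param m A [payoff_matrix()].
#' @param tol Residual tolerance for the `is_zd` verdict; the default
#'   `1e-6` suits exactly specified vectors.
#'
#' @return An object of class `zd_certificate`: list with `alpha`, `beta`,
#'   `gamma`, `residual`, `is_zd`, `baseline`, `slope` (the latter two `NA`
#'   when undefined).
#' @examples
#' zd_certificate(zd_extortion())  # baseline 3, slope 3
#' zd_certificate(tit_for_tat())   # fair: slope 1, baseline undefined
#' @export
zd_certificate <- function(p, m = payoff_matrix(), tol = 1e-6) {
  stopifnot(is_memory_one(p))
  if (anyNA(p$p)) {
    stop("strategy has an undetermined entry; use zd_complete()",
         call. = FALSE)
  }
  v <- payoff_vectors(m)
  A <- cbind(S_X = v$focal, S_Y = v$other, one = rep(1, 4))
  b <- p_tilde(unname(p$p))
  coefs <- qr.solve(qr(A), b)
  resid <- max(abs(b - drop(A %*% coefs)))
  alpha <- unname(coefs[1]); beta <- unname(coefs[2])
  gamma <- unname(coefs[3])
  eps <- 1e-12 * max(1, abs(alpha), abs(beta))
  baseline <- if (abs(alpha + beta) > eps) -gamma / (alpha + beta) else NA_real_
  slope <- if (abs(alpha) > eps) -beta / alpha else NA_real_
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, residual = resid,
         is_zd = resid <= tol, baseline = baseline, slope = slope,
         tol = tol, strategy = p$name),
    class = "zd_certificate"
  )
}

#' @export
print.zd_certificate <- function(x, ...) {
  cat("Zero-determinant certificate",
      if (!is.null(x$strategy)) paste0("for '", x$strategy, "'"), "\n")
  cat(sprintf("  alpha = %.6g, beta = %.6g, gamma = %.6g\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  max residual = %.3g (tolerance %.3g): %s\n",
              x$residual, x$tol,
              if (x$is_zd) "ZD" else "not zero-determinant"))
  if (x$is_zd) {
    cat(sprintf("  enforced relation: s_X - %s = %s (s_Y - %s)\n",
                format(x$baseline), format(x$slope), format(x$baseline)))
  }
  invisible(x)
}

#' Complete a strategy's single unknown entry so it is zero-determinant
#'
#' Given a memory-one strategy with exactly one entry marked `NA`, solves the
#' square linear system `p~ = alpha * S_X + beta * S_Y + gamma * 1` (four
#' equations in `alpha, beta, gamma` and the unknown probability) and returns
#' the completed strategy. The three known rows pin `(alpha, beta, gamma)`;
#' the remaining row then determines the missing probability uniquely.
#'
#' @param p A [memory_one_strategy()] with exactly one `NA` entry.
#' @param m A [payoff_matrix()].
#'
#' @return The completed [memory_one_strategy()], certified ZD at machine
#'   precision.
#' @examples
#' # the task's extortion strategy, with the post-exploitation entry unknown
#' zd_complete(memory_one_strategy(c(0.692, 0, NA, 0), "D"))$p[["DC"]] # 0.538
#' @export
zd_complete <- function(p, m = payoff_matrix()) {
  stopifnot(is_memory_one(p))
  unknown <- which(is.na(p$p))
  if (length(unknown) != 1L) {
    stop("exactly one strategy entry must be NA", call. = FALSE)
  }
  v <- payoff_vectors(m)
  A <- cbind(v$focal, v$other, rep(1, 4))
  b <- p_tilde(unname(p$p))
  A3 <- A[-unknown, , drop = FALSE]
  if (abs(det(A3)) < 1e-10) {
    stop("no unique completion: the three known outcomes leave the ",
         "zero-determinant system singular", call. = FALSE)
  }
  coefs <- solve(A3, b[-unknown])
  filled <- drop(A[unknown, ] %*% coefs) + if (unknown <= 2L) 1 else 0
  if (filled < -1e-12 || filled > 1 + 1e-12) {
    stop(sprintf(
      "completion infeasible: p after %s would be %.4g, outside [0, 1]",
      outcome_levels()[unknown], filled), call. = FALSE)
  }
  p_new <- p$p
  p_new[unknown] <- min(max(filled, 0), 1)
  memory_one_strategy(unname(p_new), p$initial, name = p$name)
}

#' Outcome transition matrix of two memory-one players
#'
#' @param p,q [memory_one_strategy()] objects; `p` is the focal player.
#' @return 4x4 row-stochastic matrix over outcomes `CC, CD, DC, DD`
#'   (focal perspective), rows = current outcome.
#' @export
transition_matrix <- function(p, q) {
  stopifnot(is_memory_one(p), is_memory_one(q))
  # q conditions on the outcome seen from its own side: swap CD and DC
  x <- unname(p$p)
  y <- unname(q$p)[c(1L, 3L, 2L, 4L)]
  M <- cbind(x * y, x * (1 - y), (1 - x) * y, (1 - x) * (1 - y))
  dimnames(M) <- list(outcome_levels(), outcome_levels())
  M
}

# Closed communicating classes of a finite chain, from the support graph.
closed_classes <- function(M, tol = 0) {
  n <- nrow(M)
  adj <- M > tol
  reach <- adj | diag(n) > 0
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach) > 0
  }
  classes <- list()
  seen <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (seen[i]) next
    cls <- which(reach[i, ] & reach[, i])
    if (all(which(reach[i, ]) %in% cls)) {
      classes[[length(classes) + 1L]] <- cls
    }
    seen[cls] <- TRUE
  }
  classes
}

stationary_of_irreducible <- function(M) {
  n <- nrow(M)
  A <- rbind(t(M) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(qr(A), b)
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Long-run outcome distribution of two memory-one strategies
#'
#' Computes the stationary distribution of the 4-state outcome chain induced
#' by the two strategies. When the chain has a single recurrent class the
#' stationary vector is unique and returned directly. Deterministic entries
#' can make the chain reducible (several absorbing classes); the function
#' then returns the Cesaro (long-run average) distribution started from the
#' outcome of the two initial moves, computed exactly from the absorption
#' probabilities into each closed class.
#'
#' @param p,q [memory_one_strategy()] objects; `p` is the focal player and
#'   the returned vector is indexed from `p`'s perspective.
#' @return An `outcome_distribution`: named non-negative numeric 4-vector
#'   summing to 1, with attribute `method` (`"stationary"` or `"cesaro"`).
#' @examples
#' stationary_distribution(zd_extortion(), always_cooperate()) # (7/11,0,4/11,0)
#' @export
stationary_distribution <- function(p, q) {
  M <- transition_matrix(p, q)
  r <- qr(t(M) - diag(4))$rank
  if (r == 3L) {
    pi <- stationary_of_irreducible(M)
    method <- "stationary"
  } else {
    # reducible chain: mix the closed-class stationaries by the absorption
    # probabilities from the initial state
    classes <- closed_classes(M)
    s0 <- match(outcome_of(p$initial, q$initial), outcome_levels())
    in_class <- sort(unique(unlist(classes)))
    transient <- setdiff(1:4, in_class)
    weight <- numeric(length(classes))
    for (ci in seq_along(classes)) {
      cls <- classes[[ci]]
      if (s0 %in% cls) { weight[ci] <- 1; next }
      if (length(transient) == 0L || !(s0 %in% transient)) next
      # h = P(absorbed in cls | start) on transient states
      Mtt <- M[transient, transient, drop = FALSE]
      rhs <- rowSums(M[transient, cls, drop = FALSE])
      h <- solve(diag(length(transient)) - Mtt, rhs)
      weight[ci] <- h[match(s0, transient)]
    }
    pi <- numeric(4)
    for (ci in seq_along(classes)) {
      cls <- classes[[ci]]
      pi[cls] <- pi[cls] +
        weight[ci] * stationary_of_irreducible(M[cls, cls, drop = FALSE])
    }
    method <- "cesaro"
  }
  structure(stats::setNames(pi, outcome_levels()), method = method,
            class = "outcome_distribution")
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat("Long-run outcome distribution (", attr(x, "method"), "):\n", sep = "")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Long-run per-round payoffs of two memory-one strategies
#'
#' @inheritParams stationary_distribution
#' @param m A [payoff_matrix()].
#' @return Named numeric vector `c(s_X = ..., s_Y = ...)`: the focal and
#'   co-player long-run mean payoffs per round.
#' @examples
#' expected_payoffs(zd_extortion(), always_cooperate()) # (63/11, 43/11)
#' @export
expected_payoffs <- function(p, q, m = payoff_matrix()) {
  pi <- stationary_distribution(p, q)
  v <- payoff_vectors(m)
  c(s_X = sum(pi * v$focal), s_Y = sum(pi * v$other))
}

#' Simulate long-run outcome frequencies of the two-strategy chain
#'
#' Monte-Carlo counterpart of [stationary_distribution()] /
#' [expected_payoffs()], used as an independent oracle: simulates the outcome
#' chain for `n_rounds` rounds after a burn-in and reports empirical outcome
#' frequencies and mean payoffs with batch-means standard errors (batching
#' accounts for the chain's autocorrelation).
#'
#' @inheritParams expected_payoffs
#' @param n_rounds Number of retained rounds.
#' @param seed Integer seed.
#' @param burn_in Discarded initial rounds.
#' @param n_batches Number of batches for the standard errors.
#' @return List with `freq` (outcome frequencies), `payoffs`
#'   (`s_X`, `s_Y` means) and `payoff_se` (batch-means SEs).
#' @export
simulate_outcome_freq <- function(p, q, n_rounds = 1e6, seed = NULL,
                                  burn_in = 1000, n_batches = 100,
                                  m = payoff_matrix()) {
  stopifnot(is_memory_one(p), is_memory_one(q))
  pp <- unname(p$p)
  qq <- unname(q$p)[c(1L, 3L, 2L, 4L)]
  v <- payoff_vectors(m)
  with_rng_seed(seed, {
    ntot <- n_rounds + burn_in
    u1 <- stats::runif(ntot)
    u2 <- stats::runif(ntot)
    s <- match(outcome_of(p$initial, q$initial), outcome_levels())
    states <- integer(ntot)
    for (t in seq_len(ntot)) {
      x <- u1[t] < pp[s]
      y <- u2[t] < qq[s]
      s <- if (x) { if (y) 1L else 2L } else { if (y) 3L else 4L }
      states[t] <- s
    }
    states <- states[(burn_in + 1L):ntot]
    freq <- tabulate(states, nbins = 4L) / n_rounds
    sx <- v$focal[states]
    sy <- v$other[states]
    batch <- rep(seq_len(n_batches), each = ceiling(n_rounds / n_batches),
                 length.out = n_rounds)
    bx <- tapply(sx, batch, mean)
    by <- tapply(sy, batch, mean)
    list(
      freq = stats::setNames(freq, outcome_levels()),
      payoffs = c(s_X = mean(sx), s_Y = mean(sy)),
      payoff_se = c(s_X = stats::sd(bx) / sqrt(n_batches),
                    s_Y = stats::sd(by) / sqrt(n_batches))
    )
  })
}
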