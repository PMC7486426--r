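# Shared oracles and generators for the test suite.

# A random interior memory-one strategy (probabilities bounded away from 0/1
# so the induced outcome chain is ergodic).
random_strategy <- function(lo = 0.05, hi = 0.95) {
  memory_one_strategy(runif(4, lo, hi),
                      initial = sample(c("C", "D"), 1))
}

# Press-Dyson determinant oracle for ZD membership: p~ lies in
# span{S_X, S_Y, 1} iff det[p~ | S_X | S_Y | 1] = 0.
zd_determinant <- function(p, m = payoff_matrix()) {
  v <- payoff_vectors(m)
  det(cbind(unname(p$p) - c(1, 1, 0, 0), v$focal, v$other, rep(1, 4)))
}

# Textbook balanced two-way factorial sums of squares, computed from cell
# means by brute force.
balanced_factorial_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- table(a, b)
  stopifnot(length(unique(c(n))) == 1) # balanced only
  nc <- c(n)[1]
  gm <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  ss_a <- nc * nlevels(b) * sum((ma - gm)^2)
  ss_b <- nc * nlevels(a) * sum((mb - gm)^2)
  ss_cells <- nc * sum((mab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((y - mab[interaction(a, b)])^2)
  c(a = ss_a, b = ss_b, ab = ss_ab, error = ss_err)
}

# Empirical cooperation frequency of the focal player over a long match.
match_coop_freq <- function(p, opponent, n_rounds, seed) {
  rec <- play_match(p, opponent, n_rounds, seed = seed)
  mean(rec$focal_move == "C")
}
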