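# The zero-determinant algebra: construction, certification, completion,
# stationary distributions and enforced payoff relations.

test_that("make_zd reproduces the task's strategy vectors from (ell, chi, phi)", {
  ext <- make_zd(ell = 3, chi = 3, phi = 1 / 13)
  expect_equal(unname(ext$p), c(9 / 13, 0, 7 / 13, 0), tolerance = 1e-12)
  expect_equal(ext$initial, "D")
  gen <- make_zd(ell = 5, chi = 3, phi = 1 / 11)
  expect_equal(unname(gen$p), c(1, 2 / 11, 1, 4 / 11), tolerance = 1e-12)
  expect_equal(gen$initial, "C")
  # chi = 1: a fair strategy enforcing s_X = s_Y
  fair <- make_zd(ell = 3, chi = 1, phi = 0.1)
  expect_equal(unname(fair$p), c(1, 0.5, 0.5, 0), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    pay <- expected_payoffs(fair, random_strategy())
    expect_equal(unname(pay["s_X"]), unname(pay["s_Y"]), tolerance = 1e-9)
  }
})

test_that("make_zd rejects infeasible parameters, naming the bad entry", {
  expect_error(make_zd(ell = 3, chi = 3, phi = 0.5), "infeasible")
  expect_error(make_zd(ell = 3, chi = 3, phi = 0.5), "CD")
})

test_that("certificates recover (ell, chi) for constructed ZD strategies", {
  grid <- expand.grid(ell = c(3, 4, 5), chi = c(1, 2, 3, 5))
  for (i in seq_len(nrow(grid))) {
    ell <- grid$ell[i]; chi <- grid$chi[i]
    s <- tryCatch(make_zd(ell, chi, phi = 0.05), error = function(e) NULL)
    if (is.null(s)) next
    cert <- zd_certificate(s)
    expect_lt(cert$residual, 1e-9)
    expect_true(cert$is_zd)
    if (chi > 1) { # chi = 1 means alpha + beta = 0: baseline undefined
      expect_equal(cert$baseline, ell, tolerance = 1e-9)
    }
    expect_equal(cert$slope, chi, tolerance = 1e-9)
  }
})

test_that("certificate coefficients match hand-solved linear systems", {
  ce <- zd_certificate(zd_extortion())
  expect_equal(ce$alpha, 1 / 13, tolerance = 1e-12)
  expect_equal(ce$beta, -3 / 13, tolerance = 1e-12)
  expect_equal(ce$gamma, 6 / 13, tolerance = 1e-12)
  expect_equal(ce$baseline, 3, tolerance = 1e-12)
  expect_equal(ce$slope, 3, tolerance = 1e-12)
  ct <- zd_certificate(tit_for_tat())
  expect_equal(ct$alpha, 1 / 5, tolerance = 1e-12)
  expect_equal(ct$beta, -1 / 5, tolerance = 1e-12)
  expect_equal(ct$gamma, 0, tolerance = 1e-12)
  expect_equal(ct$slope, 1, tolerance = 1e-12)
  expect_true(is.na(ct$baseline)) # alpha + beta = 0
  cn <- zd_certificate(memory_one_strategy(c(0.5, 0.5, 0.5, 0.1)))
  expect_false(cn$is_zd)
  expect_gt(cn$residual, 0.1)
})

test_that("certificate verdict agrees with the Press-Dyson determinant", {
  set.seed(17)
  for (i in 1:50) {
    s <- random_strategy(0, 1)
    cert <- zd_certificate(s, tol = 1e-8)
    d <- zd_determinant(s)
    expect_equal(cert$is_zd, abs(d) < 1e-8)
  }
  # constructed ZD strategies have determinant zero
  for (chi in c(1.5, 2, 4)) {
    s <- make_zd(3, chi, 0.04)
    expect_lt(abs(zd_determinant(s)), 1e-12)
  }
})

test_that("zd_complete pins the printed probabilities and is a fixed point", {
  s1 <- zd_complete(memory_one_strategy(c(0.692, 0, NA, 0), "D"))
  expect_equal(unname(s1$p[["DC"]]), 0.538, tolerance = 1e-9)
  s2 <- zd_complete(memory_one_strategy(c(1, 0.182, 1, NA), "C"))
  expect_equal(unname(s2$p[["DD"]]), 0.364, tolerance = 1e-9)
  s3 <- zd_complete(memory_one_strategy(c(1, 0, NA, 0), "C"))
  expect_equal(unname(s3$p[["DC"]]), 1) # tit-for-tat
  # fixed point: blanking any entry of a certified ZD strategy recovers it
  for (s in list(zd_extortion(), zd_generosity(), make_zd(4, 2, 0.05))) {
    for (k in 1:4) {
      p_hole <- s$p
      p_hole[k] <- NA
      completed <- zd_complete(memory_one_strategy(unname(p_hole), s$initial))
      expect_equal(unname(completed$p), unname(s$p), tolerance = 1e-9)
    }
  }
})

test_that("zd_complete errors on infeasible or non-unique completions", {
  expect_error(zd_complete(memory_one_strategy(c(0.1, 0.9, NA, 0.9), "C")),
               "infeasible")
  expect_error(zd_complete(memory_one_strategy(c(0.5, 0.5, 0.5, 0.5))),
               "exactly one")
})

test_that("stationary distributions match closed-form balance solutions", {
  expect_equal(as.numeric(stationary_distribution(always_defect(),
                                                  always_defect())),
               c(0, 0, 0, 1))
  # extortion vs all-C: two-state balance pi_CC * (4/13) = pi_DC * (7/13)
  pi1 <- stationary_distribution(zd_extortion(), always_cooperate())
  expect_equal(as.numeric(pi1), c(7 / 11, 0, 4 / 11, 0), tolerance = 1e-12)
  # generosity vs all-D: balance with p2 = 2/11, p4 = 4/11
  pi2 <- stationary_distribution(zd_generosity(), always_defect())
  expect_equal(as.numeric(pi2), c(0, 4 / 13, 0, 9 / 13), tolerance = 1e-12)
})

test_that("degenerate chains fall back to the Cesaro average from the start state", {
  # tit-for-tat vs itself is fully reducible: the initial moves decide
  pi_cc <- stationary_distribution(tit_for_tat(), tit_for_tat())
  expect_equal(attr(pi_cc, "method"), "cesaro")
  expect_equal(as.numeric(pi_cc), c(1, 0, 0, 0))
  tft_d <- memory_one_strategy(c(1, 0, 1, 0), "D")
  pi_dd <- stationary_distribution(tft_d, tft_d)
  expect_equal(as.numeric(pi_dd), c(0, 0, 0, 1))
  # mixed openings put tit-for-tat on the CD/DC cycle: Cesaro splits evenly
  pi_cd <- stationary_distribution(tit_for_tat(), tft_d)
  expect_equal(as.numeric(pi_cd), c(0, 0.5, 0.5, 0))
})

test_that("stationary distributions sum to 1 and match long simulations", {
  set.seed(19)
  for (i in 1:8) {
    p <- random_strategy(); q <- random_strategy()
    pi <- stationary_distribution(p, q)
    expect_equal(sum(pi), 1, tolerance = 1e-10)
    expect_true(all(pi >= 0))
    sim <- simulate_outcome_freq(p, q, n_rounds = 2e5, seed = 100 + i)
    pay <- expected_payoffs(p, q)
    expect_lt(abs(sim$payoffs["s_X"] - pay["s_X"]),
              3.5 * sim$payoff_se["s_X"] + 1e-3)
  }
})

test_that("expected payoffs verify the enforced linear relations", {
  pay <- expected_payoffs(zd_extortion(), always_cooperate())
  expect_equal(unname(pay), c(63 / 11, 43 / 11), tolerance = 1e-12)
  expect_equal(pay[["s_X"]] - 3, 3 * (pay[["s_Y"]] - 3), tolerance = 1e-12)
  pay2 <- expected_payoffs(zd_generosity(), always_defect())
  expect_equal(unname(pay2), c(35 / 13, 55 / 13), tolerance = 1e-12)
  expect_equal(pay2[["s_X"]] - 5, 3 * (pay2[["s_Y"]] - 5), tolerance = 1e-12)
  # any strategy against itself earns equal payoffs
  set.seed(23)
  for (i in 1:10) {
    s <- random_strategy()
    pay3 <- expected_payoffs(s, s)
    expect_equal(pay3[["s_X"]], pay3[["s_Y"]], tolerance = 1e-9)
  }
})

test_that("paper_strategy snaps printed decimals to exact rationals", {
  s <- paper_strategy(c(0.692, 0, 0.538, 0), "D")
  expect_identical(unname(s$p), c(9 / 13, 0, 7 / 13, 0))
  g <- paper_strategy(c(1, 0.182, 1, 0.364), "C")
  expect_identical(unname(g$p), c(1, 2 / 11, 1, 4 / 11))
  # values away from any rational are untouched
  r <- paper_strategy(c(0.25, 0.4, 0.6, 0.75))
  expect_identical(unname(r$p), c(0.25, 0.4, 0.6, 0.75))
})
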