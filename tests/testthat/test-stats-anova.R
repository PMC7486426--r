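# Between-subjects pipeline: cooperation rates, factorial ANOVA, planned
# contrast, t tests.

test_that("cooperation_rate aggregates per participant and rejects empty input", {
  tr <- generate_cohort(cohort_config(n_per_cell = 3, seed = 1))$trials
  cr <- cooperation_rate(tr)
  expect_equal(nrow(cr), 12)
  expect_true(all(cr$coop_rate >= 0 & cr$coop_rate <= 1))
  one <- tr[tr$participant_id == cr$participant_id[1], ]
  expect_equal(cr$coop_rate[1], mean(one$participant_move == "C"))
  all_c <- one; all_c$participant_move <- "C"
  expect_equal(cooperation_rate(all_c)$coop_rate, 1)
  half <- one; half$participant_move <- rep(c("C", "D"), 10)
  expect_equal(cooperation_rate(half)$coop_rate, 0.5)
  expect_error(cooperation_rate(tr[0, ]), "empty")
})

test_that("balanced two-way ANOVA matches the textbook SS decomposition", {
  set.seed(11)
  for (rep in 1:5) {
    a <- rep(c("a1", "a2"), each = 8)
    b <- rep(rep(c("b1", "b2"), each = 4), 2)
    y <- rnorm(16, mean = 2 * (a == "a2") + (b == "b2"))
    mine <- anova_two_way(y, a, b)
    ss <- balanced_factorial_ss(y, a, b)
    expect_equal(mine$table$ss, unname(ss[c("a", "b", "ab")]),
                 tolerance = 1e-10)
    expect_equal(mine$mse * mine$df_error, unname(ss["error"]),
                 tolerance = 1e-10)
  }
})

test_that("unbalanced Type III ANOVA matches car::Anova", {
  skip_if_not_installed("car")
  set.seed(12)
  n <- c(14, 17, 19, 23) # echoes the study's unequal cell sizes
  a <- factor(rep(rep(c("a1", "a2"), 2), n))
  b <- factor(rep(c("b1", "b1", "b2", "b2"), n))
  y <- rnorm(sum(n)) + 0.5 * (a == "a2") + 0.3 * (b == "b2")
  mine <- anova_two_way(y, a, b)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  ref <- car::Anova(lm(y ~ a * b), type = 3)
  expect_equal(mine$table$ss, ref[c("a", "b", "a:b"), "Sum Sq"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mine$table$F, ref[c("a", "b", "a:b"), "F value"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mine$table$p, ref[c("a", "b", "a:b"), "Pr(>F)"],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("partial eta squared identities hold on emitted tables", {
  expect_equal(round(partial_eta_sq(92.06, 1, 317), 3), 0.225)
  expect_equal(round(partial_eta_sq(7.70, 1, 317), 3), 0.024)
  expect_equal(partial_eta_sq(0, 1, 100), 0)
  set.seed(13)
  y <- rnorm(40); a <- rep(c("x", "y"), 20); b <- rep(c("u", "v"), each = 20)
  tab <- anova_two_way(y, a, b)$table
  expect_equal(tab$partial_eta_sq,
               partial_eta_sq(tab$F, tab$df1, tab$df2), tolerance = 1e-9)
})

test_that("ANOVA contracts: cell minimums, zero variance, Bonferroni caps", {
  expect_error(anova_two_way(1:5, c(1, 1, 1, 1, 2), c(1, 1, 2, 2, 1)),
               "at least 2")
  y0 <- rep(1, 16)
  a <- rep(c("a", "b"), 8); b <- rep(c("c", "d"), each = 8)
  expect_error(anova_two_way(y0, a, b), "zero error variance")
  set.seed(2)
  res <- anova_two_way(rnorm(16), a, b)
  expect_true(all(res$pairwise$p_bonferroni <= 1))
  expect_equal(nrow(res$pairwise), 6)
})

test_that("planned contrast follows its closed form and invariances", {
  cell <- factor(rep(c("c1", "c2", "c3", "c4"), each = 10))
  y_eq <- rnorm(40)
  y_eq <- y_eq - ave(y_eq, cell) # all cell means exactly 0
  res0 <- planned_contrast(y_eq, cell, c(3, -1, -1, -1))
  expect_equal(res0$t, 0, tolerance = 1e-10)
  set.seed(14)
  y <- rnorm(40, rep(c(0.8, 0.5, 0.5, 0.5), each = 10), 0.2)
  r1 <- planned_contrast(y, cell, c(1, 1, -1, -1))
  r2 <- planned_contrast(y, cell, c(2, 2, -2, -2))
  expect_equal(r1$t, r2$t, tolerance = 1e-12) # scale invariance
  # hand formula with a known MSE
  cm <- tapply(y, cell, mean)
  w <- c(3, -1, -1, -1)
  r3 <- planned_contrast(y, cell, w, mse = 0.04, df = 36)
  expect_equal(r3$t, sum(w * cm) / sqrt(0.04 * sum(w^2 / 10)),
               tolerance = 1e-12)
  expect_error(planned_contrast(y, cell, c(1, 1, 1, 1)), "sum to zero")
})

test_that("pooled t test matches stats::t.test and the r identity", {
  set.seed(15)
  x <- rnorm(20, 1); y <- rnorm(25)
  mine <- ttest_ind(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$r, sqrt(mine$t^2 / (mine$t^2 + mine$df)))
  # printed-value identities
  expect_equal(sqrt(2.99^2 / (2.99^2 + 163)), 0.228, tolerance = 5e-4)
  expect_equal(sqrt(0.76^2 / (0.76^2 + 152)), 0.0615, tolerance = 5e-4)
  z <- rnorm(10)
  same <- ttest_ind(z, z)
  expect_equal(same$t, 0)
  expect_equal(same$r, 0)
  expect_error(ttest_ind(rep(1, 5), rep(1, 5)), "pooled variance")
})
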