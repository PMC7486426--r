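# Between-subjects analyses: two-way Type III ANOVA, effect sizes, planned
# synergistic contrast, pooled t tests.

#' Per-participant cooperation rate
#'
#' @param trials A trial table (see [read_trial_table()] for the schema).
#' @return Data frame with one row per participant: `participant_id`,
#'   `strategy`, `emotion`, `n_rounds`, `coop_rate` (cooperative moves /
#'   rounds played).
#' @export
cooperation_rate <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("trial table is empty", call. = FALSE)
  }
  sp <- split(trials, trials$participant_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(participant_id = d$participant_id[1],
               strategy = d$strategy[1], emotion = d$emotion[1],
               n_rounds = nrow(d),
               coop_rate = mean(d$participant_move == "C"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F df1 / (F df1 + df2)`, the proportion of effect-plus-error
#' variance attributable to the effect.
#'
#' @param f F statistic (`>= 0`).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Effect size in `[0, 1)`.
#' @examples
#' partial_eta_sq(92.06, 1, 317) # 0.225
#' @export
partial_eta_sq <- function(f, df1, df2) {
  stopifnot(all(f >= 0), all(df1 > 0), all(df2 > 0))
  f * df1 / (f * df1 + df2)
}

# Type III sums of squares by model comparison on an effects-coded (sum to
# zero) design matrix: SS(term) = RSS(model without the term's columns) -
# RSS(full model). Equivalent to the textbook factorial decomposition on
# balanced designs.
type3_ss <- function(y, X, assign, term_ids) {
  rss <- function(cols) {
    fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  full_cols <- seq_len(ncol(X))
  rss_full <- rss(full_cols)
  ss <- vapply(term_ids, function(tid) {
    rss(full_cols[assign != tid]) - rss_full
  }, numeric(1))
  list(ss = ss, rss_full = rss_full,
       df_error = length(y) - qr(X)$rank)
}

#' Two-way factorial ANOVA (Type III, effects coding)
#'
#' Fits `y ~ A * B` with sum-to-zero coding and reports Type III sums of
#' squares, F tests, exact p-values, and partial eta squared for the two
#' main effects and the interaction. Unbalanced cells are allowed. Pairwise
#' cell-mean comparisons (pooled-MSE t tests, Bonferroni-adjusted by
#' multiplication, capped at 1) are attached.
#'
#' @param y Numeric response, one value per subject.
#' @param a,b Factors (or vectors coercible to factors).
#' @param names Labels for the two factors in the output table.
#' @return An object of class `anova_table`: list with `table` (data frame
#'   of effects), `mse`, `df_error`, `cell_means`, and `pairwise`.
#' @export
anova_two_way <- function(y, a, b, names = c("A", "B")) {
  a <- factor(a); b <- factor(b)
  stopifnot(length(y) == length(a), length(y) == length(b))
  cell <- interaction(a, b, drop = TRUE)
  if (any(table(cell) < 2)) {
    stop("every design cell needs at least 2 observations", call. = FALSE)
  }
  dat <- data.frame(y = y, a = a, b = b)
  X <- stats::model.matrix(~ a * b, dat,
                           contrasts.arg = list(a = "contr.sum",
                                                b = "contr.sum"))
  assign <- attr(X, "assign")
  t3 <- type3_ss(y, X, assign, term_ids = 1:3)
  if (t3$rss_full < 1e-12 * sum(y^2 + 1)) {
    stop("zero error variance: ANOVA undefined", call. = FALSE)
  }
  df1 <- c(nlevels(a) - 1L, nlevels(b) - 1L,
           (nlevels(a) - 1L) * (nlevels(b) - 1L))
  df2 <- t3$df_error
  mse <- t3$rss_full / df2
  fval <- (t3$ss / df1) / mse
  tab <- data.frame(
    effect = c(names[1], names[2], paste0(names[1], ":", names[2])),
    ss = t3$ss, df1 = df1, df2 = df2, F = fval,
    p = stats::pf(fval, df1, df2, lower.tail = FALSE),
    partial_eta_sq = t3$ss / (t3$ss + t3$rss_full),
    stringsAsFactors = FALSE
  )
  cm <- tapply(y, cell, mean)
  nn <- tapply(y, cell, length)
  pairs <- utils::combn(names(cm), 2)
  m_pairs <- ncol(pairs)
  pw <- data.frame(
    pair = apply(pairs, 2, paste, collapse = " vs "),
    diff = cm[pairs[1, ]] - cm[pairs[2, ]],
    t = NA_real_, p_bonferroni = NA_real_, stringsAsFactors = FALSE
  )
  for (j in seq_len(m_pairs)) {
    se <- sqrt(mse * (1 / nn[pairs[1, j]] + 1 / nn[pairs[2, j]]))
    pw$t[j] <- pw$diff[j] / se
    pw$p_bonferroni[j] <- min(1, m_pairs * 2 *
                                stats::pt(abs(pw$t[j]), df2,
                                          lower.tail = FALSE))
  }
  rownames(pw) <- NULL
  structure(list(table = tab, mse = mse, df_error = df2,
                 cell_means = cm, cell_n = nn, pairwise = pw),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Type III factorial ANOVA\n")
  tab <- x$table
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  tab$ss <- signif(tab$ss, 5)
  tab$partial_eta_sq <- round(tab$partial_eta_sq, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Error: MSE = %.5g on %d df\n", x$mse, x$df_error))
  invisible(x)
}

#' Planned (synergistic) contrast on cell means
#'
#' Tests a single-df contrast of the four cell means,
#' `t = sum(w m) / sqrt(MSE sum(w^2 / n))`. The default weights
#' `(+3, -1, -1, -1)` encode the synergistic (triangular) interaction
#' pattern: one cell elevated above the other three, rather than a crossing
#' interaction. The error term defaults to the pooled within-cell MSE with
#' `N - n_cells` df; both are overridable.
#'
#' @param y Numeric response.
#' @param cell Factor identifying the design cell of each observation; the
#'   weights are matched to `levels(cell)`.
#' @param weights Contrast weights, one per cell level, summing to zero.
#' @param mse,df Error mean square and its df; defaults to the pooled
#'   within-cell variance with `length(y) - nlevels(cell)` df.
#' @return An object of class `contrast_result`: list with `estimate`,
#'   `se`, `t`, `df`, `p` (two-sided), and `weights`.
#' @export
planned_contrast <- function(y, cell, weights = c(3, -1, -1, -1),
                             mse = NULL, df = NULL) {
  cell <- factor(cell)
  if (length(weights) != nlevels(cell)) {
    stop("need one weight per cell", call. = FALSE)
  }
  if (abs(sum(weights)) > 1e-8) {
    stop("contrast weights must sum to zero", call. = FALSE)
  }
  cm <- tapply(y, cell, mean)
  nn <- tapply(y, cell, length)
  if (is.null(mse)) {
    ss_within <- sum(tapply(y, cell, function(v) sum((v - mean(v))^2)))
    df_within <- length(y) - nlevels(cell)
    mse <- ss_within / df_within
    if (is.null(df)) df <- df_within
  } else if (is.null(df)) {
    stop("df must be supplied with a custom mse", call. = FALSE)
  }
  est <- sum(weights * cm)
  se <- sqrt(mse * sum(weights^2 / nn))
  tval <- est / se
  structure(
    list(estimate = est, se = se, t = tval, df = df,
         p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
         weights = stats::setNames(weights, levels(cell))),
    class = "contrast_result"
  )
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("Planned contrast:",
      paste(sprintf("%+g*%s", x$weights, names(x$weights)), collapse = " "),
      "\n")
  cat(sprintf("  estimate = %.4g (SE %.4g), t(%g) = %.3f, p = %.4g\n",
              x$estimate, x$se, x$df, x$t, x$p))
  invisible(x)
}

#' Independent-samples pooled t test with effect size r
#'
#' Classic two-sample t test with pooled variance; the effect size is the
#' point-biserial correlation `r = sqrt(t^2 / (t^2 + df))`.
#'
#' @param x,y Numeric samples (`n >= 2` each).
#' @return List with `t`, `df`, `p` (two-sided), `r`, and the two means.
#' @examples
#' ttest_ind(rnorm(20, 1), rnorm(20))
#' @export
ttest_ind <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tval, df = df,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       r = sqrt(tval^2 / (tval^2 + df)),
       mean_x = mean(x), mean_y = mean(y))
}
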