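# Noncentral-F a priori power analysis, following Cohen's effect-size
# conventions (as popularized by G*Power).

#' Power of a fixed-effects F test at a given total sample size
#'
#' Uses Cohen's noncentrality convention `lambda = f^2 N`, numerator df as
#' specified, and denominator df `N - n_groups`.
#'
#' @param n_total Total sample size across groups.
#' @param f Cohen's effect size f.
#' @param alpha Significance level.
#' @param n_groups Number of groups (fixes the denominator df).
#' @param df1 Numerator degrees of freedom of the tested effect.
#' @return Achieved power in `(0, 1)`.
#' @export
f_test_power <- function(n_total, f, alpha = 0.05, n_groups = 4, df1 = 1) {
  df2 <- n_total - n_groups
  stopifnot(df2 >= 1)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = f^2 * n_total, lower.tail = FALSE)
}

#' A priori total sample size for a fixed-effects F test
#'
#' Smallest total `N` such that the F test with numerator df `df1`,
#' denominator df `N - n_groups`, and noncentrality `f^2 N` attains the
#' requested power at level `alpha`. For the behavioral study's planning
#' values (`f = 0.20`, `alpha = 0.05`, power `0.95`, 4 groups, `df1 = 1`)
#' this returns 327.
#'
#' @param f Cohen's effect size f (`> 0`).
#' @param alpha Significance level, in `(0, 1)`.
#' @param power Target power, in `(0, 1)`.
#' @param n_groups Number of groups (`> 1`).
#' @param df1 Numerator degrees of freedom.
#' @param n_max Search cap; an error is raised if the target power is not
#'   reached by `n_max`.
#' @return Integer total sample size.
#' @examples
#' power_sample_size(f = 0.20, alpha = 0.05, power = 0.95,
#'                   n_groups = 4, df1 = 1) # 327
#' @export
power_sample_size <- function(f, alpha = 0.05, power = 0.95, n_groups = 4,
                              df1 = 1, n_max = 1e6) {
  stopifnot(f > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            n_groups > 1, df1 >= 1)
  n <- n_groups + 1
  while (n <= n_max) {
    if (f_test_power(n, f, alpha, n_groups, df1) >= power) return(n)
    n <- n + 1
  }
  stop("target power not reachable within n_max", call. = FALSE)
}
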