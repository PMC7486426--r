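# Multiple mediation by ordinary least squares with a seeded percentile
# bootstrap over participants.

#' Per-participant summaries used by the ANOVAs and mediation models
#'
#' Aggregates a trial table to one row per participant: cooperation rate,
#' mean expectation rating, and the proportion of rounds each emotion was
#' self-reported.
#'
#' @param trials A trial table (schema of [read_trial_table()]).
#' @return Data frame with columns `participant_id`, `strategy`, `emotion`,
#'   `coop_rate`, `expectation`, `joy`, `sadness`, `anger`, `regret`,
#'   `neutral`.
#' @export
participant_summaries <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("trial table is empty", call. = FALSE)
  }
  sp <- split(trials, trials$participant_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    props <- vapply(self_report_levels(),
                    function(e) mean(d$self_report == e), numeric(1))
    cbind(
      data.frame(participant_id = d$participant_id[1],
                 strategy = d$strategy[1], emotion = d$emotion[1],
                 coop_rate = mean(d$participant_move == "C"),
                 expectation = mean(d$expectation_rating),
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(props))
    )
  }))
  rownames(out) <- NULL
  out
}

ols_paths <- function(iv, M, dv) {
  Xm <- cbind(1, iv)
  a <- solve(crossprod(Xm), crossprod(Xm, M))[2, ]
  Xf <- cbind(1, iv, M)
  bf <- drop(solve(crossprod(Xf), crossprod(Xf, dv)))
  cprime <- bf[2]
  bcoef <- bf[-(1:2)]
  ctot <- solve(crossprod(Xm), crossprod(Xm, dv))[2]
  list(a = a, b = bcoef, direct = unname(cprime), total = unname(ctot),
       indirect = unname(a * bcoef))
}

#' Multiple mediation with bootstrap percentile confidence intervals
#'
#' Estimates, by ordinary least squares, how much of the effect of a binary
#' condition on an outcome runs through each of several mediators:
#' `a_j` (condition to mediator j), `b_j` and the direct effect `c'` (all
#' mediators plus condition to outcome in one model), and the total effect
#' `c` (condition alone). Indirect effects are `a_j b_j`; with all mediators
#' in a single outcome model the OLS identity
#' `total = direct + sum(indirect)` holds exactly. Confidence intervals are
#' percentile bootstrap, resampling participants with replacement under a
#' fixed seed.
#'
#' @param data Data frame with one row per participant.
#' @param iv Name of the condition column. A factor or character column is
#'   coded via `code_one`; a numeric column must already be 0/1.
#' @param mediators Character vector of mediator column names.
#' @param dv Name of the outcome column.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param code_one For factor/character `iv`: the level coded 1 (the other
#'   level is coded 0). Defaults to the first sorted level; the sign of
#'   every effect follows this coding.
#' @return An object of class `mediation_result`: list with `effects` (data
#'   frame of total, direct, and per-mediator indirect effects with CI
#'   bounds and bootstrap two-sided p-values), `paths` (`a`, `b`), `n_boot`,
#'   `seed`, `coding`.
#' @export
multiple_mediation <- function(data, iv, mediators, dv, n_boot = 5000,
                               seed = NULL, conf = 0.95, code_one = NULL) {
  x <- data[[iv]]
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop("numeric 'iv' must be coded 0/1", call. = FALSE)
    }
    coding <- "numeric 0/1"
  } else {
    x <- as.character(x)
    lev <- sort(unique(x))
    if (length(lev) != 2) stop("'iv' must be binary", call. = FALSE)
    if (is.null(code_one)) code_one <- lev[1]
    if (!code_one %in% lev) stop("'code_one' is not a level of iv",
                                 call. = FALSE)
    coding <- sprintf("%s = 1, %s = 0", code_one, setdiff(lev, code_one))
    x <- as.numeric(x == code_one)
  }
  if (min(table(x)) < 10) {
    stop("need at least 10 participants per condition level", call. = FALSE)
  }
  M <- as.matrix(data[, mediators, drop = FALSE])
  if (length(mediators) == 1L) colnames(M) <- mediators
  y <- data[[dv]]
  X_check <- cbind(1, x, M)
  qrX <- qr(X_check)
  if (qrX$rank < ncol(X_check)) {
    dropped <- colnames(X_check)[qrX$pivot[(qrX$rank + 1):ncol(X_check)]]
    stop("collinear mediators: ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  est <- ols_paths(x, M, y)

  nm <- length(mediators)
  boot <- with_rng_seed(seed, {
    out <- matrix(NA_real_, n_boot, nm + 2L)
    n <- length(y)
    for (r in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bi <- tryCatch(ols_paths(x[idx], M[idx, , drop = FALSE], y[idx]),
                     error = function(e) NULL)
      if (!is.null(bi)) out[r, ] <- c(bi$total, bi$direct, bi$indirect)
    }
    out
  })
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  pboot <- apply(boot, 2, function(v) {
    v <- v[!is.na(v)]
    min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  })
  effects <- data.frame(
    effect = c("total", "direct", paste0("indirect_", mediators)),
    estimate = c(est$total, est$direct, est$indirect),
    ci_lower = ci[1, ], ci_upper = ci[2, ], p_boot = pboot,
    stringsAsFactors = FALSE
  )
  rownames(effects) <- NULL
  structure(list(effects = effects,
                 paths = list(a = est$a, b = est$b),
                 n_boot = n_boot, seed = seed, conf = conf, coding = coding),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Multiple mediation (%d participants-resampled bootstraps, %g%% percentile CIs)\n",
              x$n_boot, 100 * x$conf))
  cat("  condition coding:", x$coding, "\n")
  eff <- x$effects
  eff$estimate <- round(eff$estimate, 4)
  eff$ci_lower <- round(eff$ci_lower, 4)
  eff$ci_upper <- round(eff$ci_upper, 4)
  eff$p_boot <- signif(eff$p_boot, 3)
  print(eff, row.names = FALSE)
  invisible(x)
}
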