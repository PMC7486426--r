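# Mixed (split-plot) ANOVA: two between-subject factors crossed with one
# within-subject factor (round), with Greenhouse-Geisser / Huynh-Feldt
# sphericity correction for the within-subject tests.

#' Reshape a trial table to a wide participant x round matrix
#'
#' @param trials A trial table (schema of [read_trial_table()]).
#' @param value Column to spread (default: 0/1 cooperation from
#'   `participant_move`).
#' @return List with `y` (numeric matrix, participants x rounds) and
#'   `between` (data frame of `strategy` and `emotion` per participant).
#'   Errors if any participant is missing any round (no imputation).
#' @export
trials_to_wide <- function(trials, value = c("cooperation",
                                             "expectation_rating")) {
  value <- match.arg(value)
  ids <- unique(trials$participant_id)
  rounds <- sort(unique(trials$round))
  k <- length(rounds)
  v <- if (value == "cooperation") as.numeric(trials$participant_move == "C")
       else trials$expectation_rating
  idx_p <- match(trials$participant_id, ids)
  idx_r <- match(trials$round, rounds)
  y <- matrix(NA_real_, length(ids), k,
              dimnames = list(ids, paste0("r", rounds)))
  y[cbind(idx_p, idx_r)] <- v
  if (anyNA(y)) {
    stop("incomplete within-subject data: every participant needs every ",
         "round (no imputation is performed)", call. = FALSE)
  }
  first <- !duplicated(trials$participant_id)
  between <- data.frame(strategy = trials$strategy[first],
                        emotion = trials$emotion[first],
                        row.names = trials$participant_id[first],
                        stringsAsFactors = FALSE)
  list(y = y, between = between[ids, , drop = FALSE])
}

# Greenhouse-Geisser epsilon from the residual covariance of the
# orthonormally contrast-transformed responses, and the Huynh-Feldt
# small-sample adjustment (Lecoutre-corrected form, as used by stats and
# car), capped at 1.
sphericity_eps <- function(S, error_df) {
  d <- nrow(S)
  gg <- sum(diag(S))^2 / (d * sum(S * S))
  hf <- ((error_df + 1) * d * gg - 2) / (d * (error_df - d * gg))
  c(gg = gg, hf = min(hf, 1))
}

#' Mixed ANOVA: round x two between-subject factors, with Huynh-Feldt
#' correction
#'
#' Split-plot ANOVA for a design with one within-subject factor (round) and
#' two crossed between-subject factors. Between-subject effects are tested
#' on the per-participant round means against the subjects-within-cells
#' error. Within-subject effects are computed from an orthonormal contrast
#' transformation of the round profiles (Type III sums of squares, so
#' unbalanced cells are allowed) and reported with Greenhouse-Geisser and
#' Huynh-Feldt epsilon-corrected degrees of freedom; the Huynh-Feldt
#' correction (capped at 1) is the default used for the reported p-values,
#' matching common practice when sphericity is violated but epsilon is not
#' extreme.
#'
#' @param y Numeric matrix, participants x within-levels (e.g. rounds), or a
#'   trial table (then converted via [trials_to_wide()]).
#' @param between Data frame with two factor columns (ignored when `y` is a
#'   trial table).
#' @param names Labels: within factor then the two between factors.
#' @return An object of class `mixed_anova_table`: list with `table` (all
#'   effects; within rows carry uncorrected and HF-corrected df and p),
#'   `gg_epsilon`, `hf_epsilon`.
#' @export
mixed_anova <- function(y, between = NULL,
                        names = c("round", "strategy", "emotion")) {
  if (is.data.frame(y) && "participant_move" %in% colnames(y)) {
    wide <- trials_to_wide(y)
    y <- wide$y
    between <- wide$between
  }
  stopifnot(is.matrix(y), is.data.frame(between), ncol(between) == 2,
            nrow(between) == nrow(y))
  k <- ncol(y)
  n <- nrow(y)
  a <- factor(between[[1]])
  b <- factor(between[[2]])
  dat <- data.frame(a = a, b = b)
  X <- stats::model.matrix(~ a * b, dat,
                           contrasts.arg = list(a = "contr.sum",
                                                b = "contr.sum"))
  assign <- attr(X, "assign")
  p_rank <- qr(X)$rank
  df_between_err <- n - p_rank
  df1_between <- c(nlevels(a) - 1L, nlevels(b) - 1L,
                   (nlevels(a) - 1L) * (nlevels(b) - 1L))

  # --- between-subject effects, on per-subject round means (scaled by k)
  msub <- rowMeans(y)
  t3b <- type3_ss(msub, X, assign, term_ids = 1:3)
  ss_b <- k * t3b$ss
  ss_b_err <- k * t3b$rss_full
  f_b <- (ss_b / df1_between) / (ss_b_err / df_between_err)

  # --- within-subject effects via orthonormal contrasts of the rounds
  co <- stats::contr.helmert(k)
  co <- sweep(co, 2, sqrt(colSums(co^2)), "/")
  Z <- y %*% co # n x (k-1)
  d <- k - 1L
  rssz <- function(cols) {
    fit <- stats::lm.fit(X[, cols, drop = FALSE], Z)
    R <- as.matrix(fit$residuals)
    list(ss = sum(R^2), R = R)
  }
  full_cols <- seq_len(ncol(X))
  full <- rssz(full_cols)
  ss_w_err <- full$ss
  df_w_err <- d * df_between_err
  # round main effect: drop the intercept; interactions: drop the term
  ss_round <- rssz(full_cols[assign != 0])$ss - full$ss
  ss_w_int <- vapply(1:3, function(tid) {
    rssz(full_cols[assign != tid])$ss - full$ss
  }, numeric(1))
  S <- crossprod(full$R) / df_between_err
  eps <- if (k > 2) sphericity_eps(S, df_between_err) else c(gg = 1, hf = 1)

  w_names <- c(names[1], paste0(names[1], ":", names[2]),
               paste0(names[1], ":", names[3]),
               paste0(names[1], ":", names[2], ":", names[3]))
  ss_w <- c(ss_round, ss_w_int)
  df1_w <- d * c(1L, df1_between)
  f_w <- (ss_w / df1_w) / (ss_w_err / df_w_err)
  hf <- unname(eps["hf"])

  tab <- data.frame(
    effect = c(names[2], names[3], paste0(names[2], ":", names[3]), w_names),
    within = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    ss = c(ss_b, ss_w),
    df1 = c(df1_between, df1_w),
    df2 = c(rep(df_between_err, 3), rep(df_w_err, 4)),
    stringsAsFactors = FALSE
  )
  tab$F <- c(f_b, f_w)
  tab$df1_corr <- ifelse(tab$within, hf * tab$df1, tab$df1)
  tab$df2_corr <- ifelse(tab$within, hf * tab$df2, tab$df2)
  tab$p <- stats::pf(tab$F, tab$df1_corr, tab$df2_corr, lower.tail = FALSE)
  tab$partial_eta_sq <- tab$ss /
    (tab$ss + ifelse(tab$within, ss_w_err, ss_b_err))
  structure(list(table = tab,
                 gg_epsilon = unname(eps["gg"]), hf_epsilon = hf,
                 ss_between_error = ss_b_err, df_between_error = df_between_err,
                 ss_within_error = ss_w_err, df_within_error = df_w_err),
            class = "mixed_anova_table")
}

#' @export
print.mixed_anova_table <- function(x, ...) {
  cat("Mixed ANOVA (within-subject tests Huynh-Feldt corrected, eps =",
      round(x$hf_epsilon, 4), ")\n")
  tab <- x$table
  tab$ss <- signif(tab$ss, 5); tab$F <- round(tab$F, 3)
  tab$df1_corr <- round(tab$df1_corr, 2)
  tab$df2_corr <- round(tab$df2_corr, 2)
  tab$p <- signif(tab$p, 3)
  tab$partial_eta_sq <- round(tab$partial_eta_sq, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
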