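# Cohort-level inference: covariate construction, two-level
# repeated-measures ANOVA (realized exactly as ANCOVA on within-subject
# difference scores), and covariate-adjusted regressions. All tests are
# two-sided and uncorrected, matching the reporting convention of the
# underlying analyses.

stat_row <- function(effect, statistic, df1, df2, p, coefficient = NA_real_,
                     n_used = NA_integer_, covariates = character(0)) {
  data.frame(effect = effect, statistic = statistic,
             df1 = df1, df2 = df2, p_value = p,
             coefficient = coefficient, n_used = n_used,
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Add activity covariates to a cohort table
#'
#' Computes, per subject, the region-wise mean activity of each condition
#' state (`mean_activity_0`, `mean_activity_2`) and their absolute
#' difference (`activity_difference`). Stability analyses covary the mean
#' activity of the maintained state; energy analyses covary the activity
#' difference, so that control properties are tested independently of raw
#' activation levels.
#'
#' @param cohort a `cohort` object (or any list with `table`, `states0`,
#'   `states2`).
#' @return The cohort's covariate table with the three columns appended.
#' @export
build_covariates <- function(cohort) {
  if (is.null(cohort$states0) || is.null(cohort$states2)) {
    stop("cohort is missing condition states")
  }
  tab <- cohort$table
  tab$mean_activity_0 <- colMeans(cohort$states0)
  tab$mean_activity_2 <- colMeans(cohort$states2)
  tab$activity_difference <- abs(tab$mean_activity_0 - tab$mean_activity_2)
  tab
}

#' Two-level repeated-measures ANOVA via difference-score ANCOVA
#'
#' For a within-subject factor with exactly two levels, the
#' repeated-measures ANOVA condition effect is numerically identical to an
#' ANCOVA on the per-subject difference score: the condition main effect is
#' the (covariate-adjusted) intercept test of `diff ~ covariates`, with
#' covariates mean-centered so the intercept is the adjusted mean
#' difference. With a between-subject `group` column, the group term of the
#' difference model tests the condition-by-group interaction, and the group
#' term of the subject-mean model `(A+B)/2 ~ group + covariates` tests the
#' group main effect. Incomplete rows are dropped listwise with a logged
#' count.
#'
#' @param table data.frame of per-subject outcomes and covariates.
#' @param outcome_pair character vector `c(col_A, col_B)` of the two
#'   condition columns.
#' @param between optional name of a group column.
#' @param covariates character vector of covariate column names.
#' @return A data.frame of test rows (`effect`, `statistic` = F, `df1`,
#'   `df2`, `p_value`, `coefficient`, `n_used`, `covariates`); the first
#'   row is the condition effect.
#' @export
rm_anova_2level <- function(table, outcome_pair, between = NULL,
                            covariates = character(0)) {
  stopifnot(length(outcome_pair) == 2L,
            all(c(outcome_pair, between, covariates) %in% names(table)))
  cols <- c(outcome_pair, between, covariates)
  cc <- stats::complete.cases(table[, cols, drop = FALSE])
  if (any(!cc)) ctl_log(sprintf("rm_anova_2level: %d incomplete rows dropped", sum(!cc)))
  tab <- table[cc, , drop = FALSE]
  n <- nrow(tab)
  d <- tab[[outcome_pair[1L]]] - tab[[outcome_pair[2L]]]
  mid <- (tab[[outcome_pair[1L]]] + tab[[outcome_pair[2L]]]) / 2

  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    X <- cbind(X, scale(factor_to_num(tab[[cv]]), scale = FALSE))
  }
  grp <- NULL
  if (!is.null(between)) {
    grp <- as.numeric(factor(tab[[between]])) - 1
    X <- cbind(X, scale(grp, scale = FALSE))
  }
  p <- ncol(X)
  if (n <= p) stop("too few complete rows for the requested design")
  if (qr(X)$rank < p) stop("rank-deficient design matrix")

  ols_term <- function(y, X, j) {
    fit <- stats::lm.fit(X, y)
    df2 <- n - p
    rss <- sum(fit$residuals^2)
    if (rss < 1e-24 * max(1, sum(y^2)) && abs(fit$coefficients[j]) < 1e-12) {
      # exact null (e.g. identical outcome columns): F = 0, p = 1 convention
      return(list(F = 0, p = 1, b = 0, df2 = df2))
    }
    s2 <- rss / df2
    XtXi <- chol2inv(chol(crossprod(X)))
    se <- sqrt(s2 * XtXi[j, j])
    tv <- fit$coefficients[j] / se
    list(F = tv^2, p = 2 * stats::pt(-abs(tv), df2),
         b = unname(fit$coefficients[j]), df2 = df2)
  }

  cond <- ols_term(d, X, 1L)
  out <- stat_row("condition", cond$F, 1, cond$df2, cond$p,
                  coefficient = cond$b, n_used = n, covariates = covariates)
  if (!is.null(between)) {
    jg <- p   # group column appended last
    inter <- ols_term(d, X, jg)
    main <- ols_term(mid, X, jg)
    out <- rbind(out,
                 stat_row("condition:group", inter$F, 1, inter$df2, inter$p,
                          coefficient = inter$b, n_used = n,
                          covariates = covariates),
                 stat_row("group", main$F, 1, main$df2, main$p,
                          coefficient = main$b, n_used = n,
                          covariates = covariates))
  }
  out
}

#' Covariate-adjusted regression with a standardized coefficient
#'
#' Ordinary least squares of the z-scored outcome on the z-scored predictor
#' plus (unstandardized) covariates; reports the standardized coefficient
#' `b`, its t statistic and two-sided p value. Complete cases only; a
#' near-collinear design (condition number above `1e8`) is reported with a
#' warning.
#'
#' @param table data.frame.
#' @param outcome,predictor column names.
#' @param covariates character vector of covariate column names.
#' @return A one-row data.frame (`effect`, `statistic` = t, `df1` = 1,
#'   `df2`, `p_value`, `coefficient` = standardized b, `n_used`,
#'   `covariates`).
#' @export
covariate_regression <- function(table, outcome, predictor,
                                 covariates = character(0)) {
  stopifnot(all(c(outcome, predictor, covariates) %in% names(table)))
  cols <- c(outcome, predictor, covariates)
  cc <- stats::complete.cases(table[, cols, drop = FALSE])
  if (any(!cc)) ctl_log(sprintf("covariate_regression: %d incomplete rows dropped", sum(!cc)))
  tab <- table[cc, , drop = FALSE]
  n <- nrow(tab)
  if (n < length(covariates) + 3L) stop("too few complete cases")
  y <- as.numeric(scale(tab[[outcome]]))
  xp <- as.numeric(scale(as.numeric(factor_to_num(tab[[predictor]]))))
  X <- cbind("(Intercept)" = 1, predictor = xp)
  for (cv in covariates) X <- cbind(X, as.numeric(factor_to_num(tab[[cv]])))
  colnames(X) <- c("(Intercept)", "predictor", covariates)
  kap <- kappa(X, exact = FALSE)
  if (kap > 1e8) warning(sprintf("near-collinear design (condition number %.3g)", kap))
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient design matrix")
  fit <- stats::lm.fit(X, y)
  df2 <- n - p
  s2 <- sum(fit$residuals^2) / df2
  XtXi <- chol2inv(chol(crossprod(X)))
  b <- unname(fit$coefficients["predictor"])
  se <- sqrt(s2 * XtXi[2L, 2L])
  tv <- if (se == 0) sign(b) * Inf else b / se
  stat_row(paste0(outcome, "~", predictor), tv, 1, df2,
           2 * stats::pt(-abs(tv), df2),
           coefficient = b, n_used = n, covariates = covariates)
}

# Numeric coding for two-level factors / character predictors.
factor_to_num <- function(x) {
  if (is.numeric(x)) x else as.numeric(factor(x)) - 1
}
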