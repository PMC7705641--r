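# Random-effects meta-analysis toolkit for study-level pressure summaries
# (zero-flow pressure, mean circulatory filling pressure, and their paired
# difference): DerSimonian-Laird pooling, Higgins-style prediction
# intervals, the classic Egger small-study regression, method-of-moments
# meta-regression and a between-subgroup heterogeneity test. All formulas
# are implemented directly from the moment definitions; metafor serves as
# an independent cross-check in the test suite, never as the
# implementation.

#' Validate (or assemble) a study-level summary table
#'
#' A study table has one row per study with columns `label`, `n`, effect
#' mean `y` (mmHg) and its standard error `se`; optional columns are
#' `species`, `sd` (converted to `se = sd/sqrt(n)` when `se` is absent),
#' a second paired effect `y2`/`se2` (or `sd2`), a numeric covariate such
#' as `duration_s`, and `subgroup`.
#'
#' @param df Data frame of study summaries.
#' @return The validated data frame (with `se`/`se2` filled in from SDs
#'   where needed).
#' @export
study_table <- function(df) {
  df <- as.data.frame(df)
  if (nrow(df) == 0L) stop("insufficient studies: empty table")
  if (!"y" %in% names(df)) stop("study table needs a `y` column")
  if (is.null(df$label)) df$label <- paste0("study_", seq_len(nrow(df)))
  if (is.null(df$n)) df$n <- NA_integer_
  if (is.null(df$se)) df$se <- NA_real_
  if (!is.null(df$sd)) {
    need <- is.na(df$se) & !is.na(df$sd)
    if (any(need & (is.na(df$n) | df$n < 1)))
      stop("`sd` conversion needs n >= 1")
    df$se[need] <- df$sd[need] / sqrt(df$n[need])
  }
  if (any(!is.finite(df$se) | df$se <= 0))
    stop("all `se` must be positive (supply `se`, or `sd` with `n`)")
  if (!is.null(df$y2) && is.null(df$se2)) {
    if (is.null(df$sd2)) stop("paired effect needs `se2` or `sd2`")
    df$se2 <- df$sd2 / sqrt(df$n)
  }
  if (!is.null(df$se2) && any(!is.na(df$y2) &
                              (!is.finite(df$se2) | df$se2 <= 0)))
    stop("all `se2` must be positive where `y2` is present")
  df
}

#' Read a study table from CSV
#'
#' @param path CSV with the columns described in [study_table()].
#' @param use_range If `TRUE`, rows reporting only a range (`ymin`,`ymax`)
#'   get `sd = (ymax - ymin)/4` before SE conversion; off by default.
#' @return Validated data frame.
#' @export
read_study_table <- function(path, use_range = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (use_range && all(c("ymin", "ymax") %in% names(df))) {
    if (is.null(df$sd)) df$sd <- NA_real_
    has_se <- if (is.null(df$se)) rep(FALSE, nrow(df)) else !is.na(df$se)
    need <- !has_se & is.na(df$sd)
    df$sd[need] <- (df$ymax[need] - df$ymin[need]) / 4
  }
  study_table(df)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects meta-analysis: fixed weights
#' \eqn{w_i = 1/se_i^2} give Cochran's \eqn{Q}; the between-study variance
#' is \eqn{\tau^2 = \max(0, (Q - df) / (\sum w - \sum w^2/\sum w))};
#' random-effects weights \eqn{w^*_i = 1/(se_i^2 + \tau^2)} give the pooled
#' mean, its standard error \eqn{(\sum w^*)^{-1/2}}, a normal-approximation
#' 95% CI, and \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100}.
#'
#' @param studies A [study_table()] (or data frame coercible to one) with
#'   at least columns `y` and `se`.
#' @return Object of class `meta_result`: `k`, `pooled`, `se_pooled`,
#'   `ci95`, `tau2`, `Q`, `df`, `I2`, and normalized `weights`.
#' @examples
#' pool_random_effects(data.frame(y = c(10, 14), se = c(1, 1)))
#' @export
pool_random_effects <- function(studies) {
  s <- study_table(studies)
  k <- nrow(s)
  if (k < 1L) stop("insufficient studies")
  if (k == 1L) {
    warning("single study: returning it unchanged (tau2 = 0)")
    return(structure(list(k = 1L, pooled = s$y, se_pooled = s$se,
                          ci95 = s$y + c(-1, 1) * 1.96 * s$se,
                          tau2 = 0, Q = 0, df = 0, I2 = 0, weights = 1,
                          studies = s),
                     class = "meta_result"))
  }
  w <- 1 / s$se^2
  yw <- sum(w * s$y) / sum(w)
  Q <- sum(w * (s$y - yw)^2)
  df <- k - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (s$se^2 + tau2)
  pooled <- sum(ws * s$y) / sum(ws)
  se_pooled <- 1 / sqrt(sum(ws))
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(list(k = k, pooled = pooled, se_pooled = se_pooled,
                 ci95 = pooled + c(-1, 1) * 1.96 * se_pooled,
                 tau2 = tau2, Q = Q, df = df, I2 = I2,
                 weights = ws / sum(ws), studies = s),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> k = %d: pooled = %.2f mmHg (95%% CI %.2f to %.2f)\n",
              x$k, x$pooled, x$ci95[1], x$ci95[2]))
  cat(sprintf("  tau2 = %.2f, Q = %.2f (df = %d), I2 = %.1f%%\n",
              x$tau2, x$Q, x$df, x$I2))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Prediction interval for a new study
#'
#' Higgins-Thompson-Spiegelhalter form:
#' pooled \eqn{\pm t_{0.975, k-2} \sqrt{\tau^2 + se_{pooled}^2}}. Widens
#' the confidence interval by the between-study variance, answering where
#' the effect of a *new* study is expected to fall.
#'
#' @param res A `meta_result` with at least 3 studies.
#' @return Numeric `c(lo, hi)` in mmHg.
#' @export
prediction_interval <- function(res) {
  stopifnot(inherits(res, "meta_result"))
  if (res$k < 3L) stop("prediction interval undefined for k < 3")
  half <- stats::qt(0.975, df = res$k - 2) *
    sqrt(res$tau2 + res$se_pooled^2)
  res$pooled + c(-1, 1) * half
}

#' Pool within-study paired differences
#'
#' For studies reporting two effects (e.g. zero-flow pressure and mean
#' circulatory filling pressure measured in the same animals), pools
#' \eqn{d_i = y_i - y_{2,i}} with
#' \eqn{se_{d,i} = \sqrt{se_i^2 + se_{2,i}^2}} by [pool_random_effects()].
#' Within-study independence of the two arms is assumed (correlations are
#' rarely reported); this is conservative for positively correlated arms
#' and the result carries a note saying so.
#'
#' @param studies A [study_table()] where every row has `y2` and `se2`.
#' @return A `meta_result` for the difference.
#' @export
pool_difference <- function(studies) {
  s <- study_table(studies)
  if (is.null(s$y2) || any(is.na(s$y2)))
    stop("not a paired record: every study needs `y2` (and `se2`)")
  d <- data.frame(label = s$label, n = s$n,
                  y = s$y - s$y2, se = sqrt(s$se^2 + s$se2^2))
  out <- pool_random_effects(d)
  out$note <- "paired SEs assume within-study independence of the two arms"
  out
}

#' Egger regression test for small-study bias
#'
#' Classic Egger test: ordinary least squares of the standardized effect
#' \eqn{y_i/se_i} on precision \eqn{1/se_i}; the intercept estimates funnel
#' asymmetry and is tested two-sided against t with k-2 df.
#'
#' @param studies A [study_table()] with at least 3 studies.
#' @return List `intercept`, `se_intercept`, `t`, `p`, `degenerate`.
#' @export
egger_test <- function(studies) {
  s <- study_table(studies)
  k <- nrow(s)
  if (k < 3L) stop("underdetermined: Egger test needs at least 3 studies")
  prec <- 1 / s$se
  z <- s$y / s$se
  if (stats::var(prec) < 1e-14 || stats::var(z) < 1e-14) {
    warning("Egger regression is degenerate (no spread in precision or effects)")
    return(list(intercept = NA_real_, se_intercept = NA_real_,
                t = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  f <- stats::lm(z ~ prec)
  sm <- summary(f)$coefficients
  tval <- sm[1, 1] / sm[1, 2]
  list(intercept = unname(sm[1, 1]), se_intercept = unname(sm[1, 2]),
       t = unname(tval),
       p = 2 * stats::pt(-abs(tval), df = k - 2),
       degenerate = FALSE)
}

#' Random-effects meta-regression (method of moments)
#'
#' Weighted least squares of the effect on one covariate. The residual
#' between-study variance comes from the moment equation on the residual
#' heterogeneity statistic,
#' \eqn{\tau^2 = \max(0,(Q_E - (k-2)) / (tr(W) - tr((X'WX)^{-1}X'W^2X)))},
#' after which the slope is re-estimated with weights
#' \eqn{1/(se_i^2 + \tau^2)} and tested two-sided against t with k-2 df.
#'
#' @param studies A [study_table()] with at least 4 studies.
#' @param covariate Numeric vector (per study) or the name of a column of
#'   `studies` (e.g. `"duration_s"`, duration of flow cessation).
#' @return List `intercept`, `slope`, `se_slope`, `t`, `p`,
#'   `tau2_residual`.
#' @export
meta_regression <- function(studies, covariate) {
  s <- study_table(studies)
  k <- nrow(s)
  if (k < 4L) stop("meta-regression needs at least 4 studies")
  x <- if (is.character(covariate) && length(covariate) == 1L) {
    if (!covariate %in% names(s)) stop("no column `", covariate, "`")
    s[[covariate]]
  } else as.numeric(covariate)
  if (length(x) != k) stop("covariate length must match number of studies")
  if (stats::var(x) <= 0) stop("covariate constant")

  X <- cbind(1, x)
  fitw <- function(wvec) {
    W <- diag(wvec)
    XtWX <- crossprod(X, W %*% X)
    beta <- solve(XtWX, crossprod(X, wvec * s$y))
    list(beta = beta, XtWX = XtWX)
  }
  w <- 1 / s$se^2
  f0 <- fitw(w)
  resid0 <- s$y - X %*% f0$beta
  QE <- sum(w * resid0^2)
  trP <- sum(w) - sum(diag(solve(f0$XtWX,
                                 crossprod(X, (w^2) * X))))
  tau2 <- max(0, (QE - (k - 2)) / trP)

  ws <- 1 / (s$se^2 + tau2)
  f1 <- fitw(ws)
  V <- solve(f1$XtWX)
  se_slope <- sqrt(V[2, 2])
  tval <- f1$beta[2] / se_slope
  list(intercept = unname(f1$beta[1]), slope = unname(f1$beta[2]),
       se_slope = se_slope, t = unname(tval),
       p = 2 * stats::pt(-abs(tval), df = k - 2),
       tau2_residual = tau2)
}

#' Between-subgroup heterogeneity test
#'
#' Pools each subgroup separately by DerSimonian-Laird, then tests whether
#' the subgroup means share a common value:
#' \eqn{Q_{between} = \sum_g w_g (\hat y_g - \hat y_{all})^2} with
#' \eqn{w_g = 1/se_{pooled,g}^2} and \eqn{\hat y_{all}} their weighted
#' mean, referred to chi-square with (groups - 1) df. Subgroups with fewer
#' than 2 studies are excluded with a warning.
#'
#' @param studies A [study_table()].
#' @param by Name of the subgroup column (default `"subgroup"`, falling
#'   back to `"species"`).
#' @return List `Q_between`, `df`, `p`, `subgroups` (per-group
#'   `meta_result`s).
#' @export
subgroup_heterogeneity <- function(studies, by = NULL) {
  s <- study_table(studies)
  if (is.null(by))
    by <- if (!is.null(s$subgroup)) "subgroup" else "species"
  if (!by %in% names(s)) stop("no subgroup column `", by, "`")
  groups <- split(s, s[[by]])
  small <- names(groups)[vapply(groups, nrow, integer(1)) < 2L]
  if (length(small) > 0L) {
    warning("excluding subgroup(s) with < 2 studies: ",
            paste(small, collapse = ", "))
    groups <- groups[!names(groups) %in% small]
  }
  if (length(groups) < 2L)
    stop("need at least 2 subgroups with >= 2 studies")
  pooled <- lapply(groups, pool_random_effects)
  wg <- vapply(pooled, function(p) 1 / p$se_pooled^2, numeric(1))
  yg <- vapply(pooled, function(p) p$pooled, numeric(1))
  yall <- sum(wg * yg) / sum(wg)
  Qb <- sum(wg * (yg - yall)^2)
  df <- length(groups) - 1L
  list(Q_between = Qb, df = df,
       p = stats::pchisq(Qb, df, lower.tail = FALSE),
       subgroups = pooled)
}
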