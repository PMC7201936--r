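#' Wald ratio estimate for a single variant
#'
#' Per-variant causal estimate: the outcome association divided by the
#' exposure association, with the first-order delta-method standard error
#' `se_outcome / |beta_exposure|` (the exposure uncertainty is ignored,
#' consistent with inverse-variance weighting).
#'
#' @param beta_exposure,se_exposure Exposure association and its se.
#' @param beta_outcome,se_outcome Outcome association and its se.
#' @param second_order Include the second-order term
#'   `se_exposure^2 * beta_outcome^2 / beta_exposure^4` in the variance.
#' @return List with `beta` and `se`.
#' @examples
#' wald_ratio(0.1, 0.01, 0.05, 0.01)
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                       second_order = FALSE) {
  if (beta_exposure == 0)
    input_error("Wald ratio undefined for a zero exposure beta")
  v <- se_outcome^2 / beta_exposure^2
  if (second_order)
    v <- v + se_exposure^2 * beta_outcome^2 / beta_exposure^4
  list(beta = beta_outcome / beta_exposure, se = sqrt(v))
}

new_mr_fit <- function(method, exposure, beta, se, n_variants, Q = NA_real_,
                       Q_df = NA_real_, mean_f = NA_real_,
                       egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                       random_effects = FALSE) {
  ci <- beta + c(-1, 1) * 1.96 * se
  fit <- list(method = method, exposure = exposure, beta = beta, se = se,
              ci_lower = ci[1], ci_upper = ci[2],
              or = exp(beta), or_ci_lower = exp(ci[1]), or_ci_upper = exp(ci[2]),
              Q = Q, Q_df = Q_df,
              Q_pval = if (is.na(Q) || Q_df < 1) NA_real_
                       else stats::pchisq(Q, Q_df, lower.tail = FALSE),
              egger_intercept = egger_intercept,
              egger_intercept_se = egger_intercept_se,
              egger_intercept_pval = if (is.na(egger_intercept)) NA_real_
                                     else z_pvalue(egger_intercept / egger_intercept_se),
              mean_f = mean_f, n_variants = n_variants,
              pval = z_pvalue(beta / se),
              random_effects = random_effects)
  class(fit) <- "mr_fit"
  fit
}

#' Inverse-variance-weighted MR estimate
#'
#' Combines per-variant Wald ratios in a fixed-effect meta-analysis, i.e.
#' weighted least squares of the outcome betas on the exposure betas through
#' the origin with weights `1/se_y^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`, `se = sum(w bx^2)^(-1/2)`.
#' Cochran's Q (heterogeneity of the ratio estimates) and the mean
#' instrument F statistic are attached. A multiplicative random-effects
#' variant inflates the se by `sqrt(max(1, Q/df))`.
#'
#' @param h A [harmonize()]d set with a single exposure, or one of a
#'   multi-exposure set selected via `exposure`.
#' @param exposure Exposure label (defaults to the only/first exposure).
#' @param random_effects Apply the multiplicative random-effects inflation.
#' @return An object of class `mr_fit`.
#' @export
mr_ivw <- function(h, exposure = h$exposures[1], random_effects = FALSE) {
  bx <- h_bx(h, exposure); by <- h_by(h); sey <- h_sey(h)
  if (is.null(bx)) input_error("exposure '%s' not in harmonized set", exposure)
  n <- length(bx)
  if (n < 2L)
    input_error("IVW requires >= 2 variants; use wald_ratio() for a single variant")
  w <- 1 / sey^2
  denom <- sum(w * bx^2)
  beta <- sum(w * bx * by) / denom
  se <- sqrt(1 / denom)
  Q <- sum(w * (by - beta * bx)^2)
  df <- n - 1L
  if (random_effects) se <- se * sqrt(max(1, Q / df))
  new_mr_fit("ivw", exposure, beta, se, n, Q = Q, Q_df = df,
             mean_f = mean_f_values(bx, h_sex(h, exposure)),
             random_effects = random_effects)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas *with*
#' an intercept (weights `1/se_y^2`), after orienting all exposure betas
#' non-negative (flipping the paired outcome betas). The slope is the
#' pleiotropy-adjusted causal estimate; a non-zero intercept indicates
#' directional pleiotropy. Fixed-effect (meta-analysis) standard errors are
#' used, matching [mr_ivw()].
#'
#' @inheritParams mr_ivw
#' @return An `mr_fit` with `egger_intercept` fields populated and
#'   `Q_df = n - 2`.
#' @export
mr_egger <- function(h, exposure = h$exposures[1]) {
  bx <- h_bx(h, exposure); by <- h_by(h); sey <- h_sey(h)
  if (is.null(bx)) input_error("exposure '%s' not in harmonized set", exposure)
  n <- length(bx)
  if (n < 3L) input_error("MR-Egger requires >= 3 variants (got %d)", n)
  flip <- sign(bx) < 0
  bx <- abs(bx); by <- ifelse(flip, -by, by)
  w <- 1 / sey^2
  X <- cbind(1, bx)
  A <- crossprod(X * sqrt(w))
  V <- solve(A)
  coefs <- drop(V %*% crossprod(X * w, by))
  resid <- by - drop(X %*% coefs)
  Q <- sum(w * resid^2)
  new_mr_fit("egger", exposure, coefs[2], sqrt(V[2, 2]), n,
             Q = Q, Q_df = n - 2L,
             mean_f = mean_f_values(bx, h_sex(h, exposure)),
             egger_intercept = coefs[1], egger_intercept_se = sqrt(V[1, 1]))
}

#' Cochran's Q heterogeneity statistic for an IVW fit
#'
#' `Q = sum(w_j (by_j - beta_hat * bx_j)^2)` with `w_j = 1/se_y_j^2`,
#' referred to a chi-square with `n - 1` degrees of freedom.
#'
#' @param h The harmonized set the fit was computed on.
#' @param fit The [mr_ivw()] fit.
#' @return List with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(h, fit) {
  if (!inherits(fit, "mr_fit") || fit$method != "ivw")
    input_error("'fit' must be an IVW mr_fit")
  bx <- h_bx(h, fit$exposure); by <- h_by(h); sey <- h_sey(h)
  n <- length(bx)
  if (n != fit$n_variants)
    input_error("fit was computed on %d variants but the set has %d",
                fit$n_variants, n)
  if (n < 2L) input_error("Q undefined for a single variant (df would be 0)")
  w <- 1 / sey^2
  Q <- sum(w * (by - fit$beta * bx)^2)
  list(Q = Q, df = n - 1L, pval = stats::pchisq(Q, n - 1L, lower.tail = FALSE))
}

mean_f_values <- function(beta, se) mean((beta / se)^2)

#' Mean instrument F statistic
#'
#' Mean over instruments of the squared z statistic `(beta/se)^2`; the
#' conventional instrument-strength diagnostic (F > 10 rule of thumb).
#'
#' @param stats A `sumstats` data frame of instruments.
#' @return A scalar.
#' @export
mean_f <- function(stats) {
  validate_sumstats(stats)
  if (nrow(stats) == 0L) input_error("empty instrument set")
  mean_f_values(stats$beta, stats$se)
}

#' Odds ratio with 95% confidence interval from a log-odds estimate
#'
#' @param beta Log odds ratio (per category change for the body-size
#'   exposures).
#' @param se Its standard error.
#' @return List with `or`, `ci_lower`, `ci_upper`
#'   (`exp(beta +/- 1.96 se)`).
#' @examples
#' to_odds_ratio(0.399, 0.060)
#' @export
to_odds_ratio <- function(beta, se) {
  list(or = exp(beta), ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se))
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s MR estimate for '%s' (%d variants%s)\n",
              toupper(x$method), x$exposure, x$n_variants,
              if (isTRUE(x$random_effects)) ", random effects" else ""))
  cat(sprintf("  beta %.*f (se %.*f), 95%% CI [%.*f, %.*f], p = %.3g\n",
              digits, x$beta, digits, x$se, digits, x$ci_lower,
              digits, x$ci_upper, x$pval))
  cat(sprintf("  OR %.*f [%.*f, %.*f]\n", digits, x$or, digits,
              x$or_ci_lower, digits, x$or_ci_upper))
  if (!is.na(x$Q))
    cat(sprintf("  Cochran Q %.2f on %d df (p = %.3g); mean F %.1f\n",
                x$Q, x$Q_df, x$Q_pval, x$mean_f))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept %.*f (se %.*f, p = %.3g)\n",
                digits, x$egger_intercept, digits, x$egger_intercept_se,
                x$egger_intercept_pval))
  invisible(x)
}

#' Tabulate MR fits for export
#'
#' @param ... `mr_fit` and/or `mvmr_fit` objects.
#' @return One row per method x exposure with estimate, se, CI, OR, Q,
#'   Egger intercept, mean/conditional F and variant count.
#' @export
mr_results_table <- function(...) {
  fits <- list(...)
  rows <- lapply(fits, function(f) {
    if (inherits(f, "mvmr_fit")) {
      data.frame(method = "mvmr", exposure = f$exposures,
                 beta = f$beta, se = f$se,
                 ci_lower = f$ci_lower, ci_upper = f$ci_upper,
                 or = f$or, or_ci_lower = f$or_ci_lower,
                 or_ci_upper = f$or_ci_upper, pval = f$pval,
                 Q = f$Q, Q_df = f$Q_df,
                 egger_intercept = NA_real_,
                 f_statistic = f$conditional_f,
                 n_variants = f$n_variants, stringsAsFactors = FALSE)
    } else {
      data.frame(method = f$method, exposure = f$exposure, beta = f$beta,
                 se = f$se, ci_lower = f$ci_lower, ci_upper = f$ci_upper,
                 or = f$or, or_ci_lower = f$or_ci_lower,
                 or_ci_upper = f$or_ci_upper, pval = f$pval,
                 Q = f$Q, Q_df = f$Q_df,
                 egger_intercept = f$egger_intercept,
                 f_statistic = f$mean_f,
                 n_variants = f$n_variants, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
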