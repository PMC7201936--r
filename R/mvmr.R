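#' Multivariable MR: joint direct effects of k exposures
#'
#' Weighted least squares of the outcome betas on the k columns of exposure
#' betas with no intercept and weights `1/se_y^2`, solved by the weighted
#' normal equations. Each coefficient is the *direct* effect of that
#' exposure on the outcome, conditional on the other exposures.
#' Fixed-effect standard errors come from `(X'WX)^{-1}`; a multiplicative
#' random-effects option inflates them by `sqrt(max(1, Q/df))` with
#' `df = n_variants - k`. With a single exposure the fit coincides exactly
#' with [mr_ivw()]. Per-exposure conditional F statistics (instrument
#' strength given the other exposures) are attached when k >= 2.
#'
#' @param h A [harmonize()]d set with k >= 1 exposures.
#' @param random_effects Inflate ses by `sqrt(max(1, Q/df))`.
#' @return An object of class `mvmr_fit`: per-exposure vectors `beta`,
#'   `se`, `ci_lower`, `ci_upper`, `or`, `or_ci_*`, `pval`,
#'   `conditional_f`, plus joint `Q`, `Q_df`, `Q_pval` and `n_variants`.
#' @export
mvmr_fit <- function(h, random_effects = FALSE) {
  k <- length(h$exposures)
  by <- h_by(h); sey <- h_sey(h)
  n <- length(by)
  if (n <= k)
    input_error("multivariable MR needs more variants than exposures (%d <= %d)",
                n, k)
  X <- sapply(h$exposures, function(l) h_bx(h, l))
  X <- matrix(X, nrow = n, dimnames = list(NULL, h$exposures))
  w <- 1 / sey^2
  Xw <- X * sqrt(w)
  qrX <- qr(Xw)
  if (qrX$rank < k) {
    cc <- abs(stats::cor(X))
    pairs <- which(cc > 1 - 1e-8 & upper.tri(cc), arr.ind = TRUE)
    culprit <- if (nrow(pairs)) {
      paste(apply(pairs, 1L, function(p)
        paste(h$exposures[p], collapse = " ~ ")), collapse = "; ")
    } else paste(h$exposures, collapse = ", ")
    input_error("exposure-beta design is rank deficient (collinear exposures: %s)",
                culprit)
  }
  A <- crossprod(Xw)
  V <- solve(A)
  beta <- drop(V %*% crossprod(X * w, by))
  se <- sqrt(diag(V))
  Q <- sum(w * (by - drop(X %*% beta))^2)
  df <- n - k
  if (random_effects) se <- se * sqrt(max(1, Q / df))
  ci_l <- beta - 1.96 * se
  ci_u <- beta + 1.96 * se
  cond_f <- if (k >= 2L) {
    vapply(h$exposures, function(l) conditional_f(h, l), numeric(1))
  } else {
    stats::setNames(mean_f_values(X[, 1], h_sex(h, h$exposures[1])),
                    h$exposures)
  }
  fit <- list(exposures = h$exposures,
              beta = stats::setNames(beta, h$exposures),
              se = stats::setNames(se, h$exposures),
              ci_lower = stats::setNames(ci_l, h$exposures),
              ci_upper = stats::setNames(ci_u, h$exposures),
              or = exp(stats::setNames(beta, h$exposures)),
              or_ci_lower = exp(stats::setNames(ci_l, h$exposures)),
              or_ci_upper = exp(stats::setNames(ci_u, h$exposures)),
              pval = z_pvalue(beta / se),
              conditional_f = cond_f,
              Q = Q, Q_df = df,
              Q_pval = stats::pchisq(Q, df, lower.tail = FALSE),
              n_variants = n, random_effects = random_effects)
  class(fit) <- "mvmr_fit"
  fit
}

#' @export
print.mvmr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Multivariable MR fit: %d exposures, %d variants (joint Q %.2f on %d df, p = %.3g)\n",
              length(x$exposures), x$n_variants, x$Q, x$Q_df, x$Q_pval))
  for (l in x$exposures)
    cat(sprintf("  %-10s direct beta %.*f (se %.*f) 95%% CI [%.*f, %.*f]  OR %.*f [%.*f, %.*f]  F %.1f\n",
                l, digits, x$beta[l], digits, x$se[l], digits, x$ci_lower[l],
                digits, x$ci_upper[l], digits, x$or[l], digits,
                x$or_ci_lower[l], digits, x$or_ci_upper[l],
                x$conditional_f[l]))
  invisible(x)
}

#' Conditional instrument-strength F statistic
#'
#' Strength of one exposure's instruments conditional on the other modelled
#' exposures: the named exposure's betas are regressed on the other
#' exposures' betas (weighted by that exposure's inverse variances) and the
#' weighted residual sum of squares is divided by `n_variants - k + 1`.
#' When the exposure-beta columns are orthogonal this approaches the
#' marginal mean F; duplicated columns give 0.
#'
#' @param h A harmonized set with k >= 2 exposures.
#' @param exposure Label of the exposure whose conditional strength is
#'   required.
#' @return A non-negative scalar.
#' @export
conditional_f <- function(h, exposure) {
  k <- length(h$exposures)
  if (k < 2L)
    input_error("conditional F needs >= 2 exposures; use mean_f() for one")
  if (!exposure %in% h$exposures)
    input_error("exposure '%s' not in harmonized set", exposure)
  target <- h_bx(h, exposure)
  others <- sapply(setdiff(h$exposures, exposure), function(l) h_bx(h, l))
  others <- matrix(others, nrow = length(target))
  w <- 1 / h_sex(h, exposure)^2
  sw <- sqrt(w)
  # no intercept: mirrors the origin-constrained joint fit
  resid <- qr.resid(qr(others * sw), target * sw)
  sum(resid^2) / (length(target) - k + 1)
}

#' Decompose a total effect into direct and indirect components
#'
#' In the linear path model, indirect (adult-mediated) effect = total -
#' direct. Its standard error uses the independence approximation
#' `sqrt(se_total^2 + se_direct^2)` and is flagged approximate (the two
#' estimates share instruments, so this typically overstates the
#' uncertainty). A life-course scenario label is assigned:
#' * `"mediated"` - the direct-effect CI covers 0 while the total-effect CI
#'   excludes 0 (the coronary-artery-disease / type-2-diabetes pattern);
#' * `"direct-only"` - direct and total agree (|difference| < 20% of
#'   |total| with overlapping CIs; the breast-cancer pattern);
#' * `"both"` - otherwise.
#' The label is a reporting heuristic, not a formal test.
#'
#' @param total Univariable [mr_ivw()] fit (the total effect).
#' @param direct [mvmr_fit()] result containing the same exposure.
#' @param exposure Exposure label in `direct`.
#' @return Object of class `mr_decomposition` with the three effects, the
#'   approximate indirect se/CI and the `scenario` label.
#' @export
decompose_effects <- function(total, direct, exposure = total$exposure) {
  if (!inherits(total, "mr_fit")) input_error("'total' must be an mr_fit")
  if (!inherits(direct, "mvmr_fit")) input_error("'direct' must be an mvmr_fit")
  if (!exposure %in% direct$exposures)
    input_error("exposure '%s' not in the multivariable fit", exposure)
  d_beta <- direct$beta[[exposure]]
  d_se <- direct$se[[exposure]]
  ind <- total$beta - d_beta
  ind_se <- sqrt(total$se^2 + d_se^2)
  d_covers0 <- direct$ci_lower[[exposure]] <= 0 && direct$ci_upper[[exposure]] >= 0
  t_excludes0 <- total$ci_lower > 0 || total$ci_upper < 0
  overlap <- total$ci_lower <= direct$ci_upper[[exposure]] &&
    direct$ci_lower[[exposure]] <= total$ci_upper
  close <- abs(ind) < 0.2 * abs(total$beta) && overlap
  scenario <- if (d_covers0 && t_excludes0) "mediated"
              else if (close) "direct-only"
              else "both"
  structure(list(exposure = exposure,
                 total = total$beta, total_se = total$se,
                 direct = d_beta, direct_se = d_se,
                 indirect = ind, indirect_se = ind_se,
                 indirect_ci_lower = ind - 1.96 * ind_se,
                 indirect_ci_upper = ind + 1.96 * ind_se,
                 indirect_se_approximate = TRUE,
                 scenario = scenario),
            class = "mr_decomposition")
}

#' @export
print.mr_decomposition <- function(x, digits = 3, ...) {
  cat(sprintf("Effect decomposition for '%s'\n", x$exposure))
  cat(sprintf("  total    %.*f (se %.*f)\n", digits, x$total, digits, x$total_se))
  cat(sprintf("  direct   %.*f (se %.*f)\n", digits, x$direct, digits, x$direct_se))
  cat(sprintf("  indirect %.*f (se %.*f, approximate; 95%% CI [%.*f, %.*f])\n",
              digits, x$indirect, digits, x$indirect_se,
              digits, x$indirect_ci_lower, digits, x$indirect_ci_upper))
  cat(sprintf("  scenario: %s\n", x$scenario))
  invisible(x)
}

#' Negative-control analysis on age at menarche
#'
#' Age at menarche can only be influenced by early-life body size: adult
#' body size is realised after puberty, so within the multivariable
#' framework its direct effect on menarche must be null and the early-life
#' direct effect must coincide with its univariable total. This function
#' runs the joint fit and reports whether both checks pass.
#'
#' @param h Harmonized set with exposures early and adult body size and the
#'   menarche trait as outcome.
#' @param h_early Univariable harmonized set (early instruments only,
#'   menarche outcome) for the total effect.
#' @param adult Label of the adult exposure in `h` (default
#'   second exposure).
#' @param early Label of the early exposure (default first).
#' @return List of class `negative_control`: `mvmr` fit, `total` (early
#'   univariable fit), logical checks `adult_null` (adult direct-effect CI
#'   covers 0) and `early_consistent` (|direct - total| within 1.96 of the
#'   combined se), and overall `pass`.
#' @export
negative_control_analysis <- function(h, h_early,
                                      early = h$exposures[1],
                                      adult = h$exposures[2]) {
  fit <- mvmr_fit(h)
  total <- mr_ivw(h_early, exposure = early)
  adult_null <- fit$ci_lower[[adult]] <= 0 && fit$ci_upper[[adult]] >= 0
  diff <- fit$beta[[early]] - total$beta
  diff_se <- sqrt(fit$se[[early]]^2 + total$se^2)
  early_consistent <- abs(diff) <= 1.96 * diff_se
  structure(list(mvmr = fit, total = total,
                 adult_null = adult_null,
                 early_consistent = early_consistent,
                 early_direct_minus_total = diff,
                 pass = adult_null && early_consistent),
            class = "negative_control")
}

#' @export
print.negative_control <- function(x, ...) {
  cat("Negative-control analysis (age at menarche outcome)\n")
  cat(sprintf("  adult direct effect null: %s\n",
              if (x$adult_null) "yes (CI covers 0)" else "NO"))
  cat(sprintf("  early direct ~= early total: %s (difference %.3f)\n",
              if (x$early_consistent) "yes" else "NO",
              x$early_direct_minus_total))
  cat(sprintf("  overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
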