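#' Per-variant association scan
#'
#' Regresses a phenotype on each variant's dosage in turn with covariate
#' adjustment. Categorical body-size phenotypes are coded 0/1/2 and analysed
#' by linear regression, i.e. assuming the per-allele effect of moving from
#' the lowest to the middle category equals that of moving from the middle
#' to the highest. Scans of the early-life measure conventionally add
#' `month_of_birth` to the covariates (relative age within the school year
#' may bias self-report). Two-sided p-values use the normal approximation.
#'
#' Sex-stratified scans are obtained by filtering the cohort on the sex
#' covariate first (see [filter_cohort()]).
#'
#' @param cohort A [simulate_cohort()] result (or [read_cohort()]).
#' @param phenotype Name of a column of `cohort$phenotypes`.
#' @param covariates Character vector of covariate column names (may be
#'   empty). An intercept is always included.
#' @param variants Optional variant-id subset; defaults to all panel
#'   variants.
#' @param model `"linear"` (least squares, default) or `"logistic"`
#'   (per-variant logistic regression; betas are log odds ratios).
#' @return A `sumstats` data frame with columns `SNP`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `samplesize`. Variants
#'   with a constant dosage column are reported with beta 0, infinite se,
#'   p-value 1 and are listed in `attr(, "degenerate")`.
#' @examples
#' spec <- scenario_spec(n_variants = 10, seed = 5)
#' ch <- simulate_cohort(simulate_panel(spec), spec, 300)
#' head(gwas_scan(ch, "early_reported", c("age", "sex", "month_of_birth")))
#' @export
gwas_scan <- function(cohort, phenotype, covariates = character(),
                 variants = NULL, model = c("linear", "logistic")) {
  model <- match.arg(model)
  ph <- cohort$phenotypes
  if (!phenotype %in% names(ph))
    input_error("phenotype '%s' not found in cohort", phenotype)
  missing_cov <- setdiff(covariates, names(ph))
  if (length(missing_cov))
    input_error("covariate(s) not found in cohort: %s",
                paste(missing_cov, collapse = ", "))
  y <- as.numeric(ph[[phenotype]])
  if (stats::var(y) == 0)
    input_error("phenotype '%s' has zero variance", phenotype)
  G <- cohort$genotypes
  if (!is.null(variants)) {
    missing_v <- setdiff(variants, colnames(G))
    if (length(missing_v))
      input_error("variant(s) not in cohort: %s", paste(missing_v, collapse = ", "))
    G <- G[, variants, drop = FALSE]
  }
  vtab <- cohort$variants[match(colnames(G), cohort$variants$SNP), ]
  n <- length(y)
  X <- cbind(intercept = 1, as.matrix(ph[covariates]))
  if (model == "linear") {
    res <- scan_linear(y, G, X)
  } else {
    res <- scan_logistic(y, G, X)
  }
  out <- data.frame(
    SNP = colnames(G),
    effect_allele = vtab$effect_allele,
    other_allele = vtab$other_allele,
    eaf = colMeans(G) / 2,
    beta = res$beta,
    se = res$se,
    pval = res$pval,
    samplesize = n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sumstats", "data.frame")
  attr(out, "degenerate") <- colnames(G)[res$degenerate]
  attr(out, "phenotype") <- phenotype
  out
}

# vectorised per-variant OLS by Frisch-Waugh-Lovell: residualise phenotype
# and dosages on the covariates once (normal equations, BLAS-3), then one
# simple regression per variant
scan_linear <- function(y, G, X) {
  n <- length(y)
  XtX <- crossprod(X)
  p <- qr(XtX)$rank
  proj <- function(v) v - X %*% solve(XtX, crossprod(X, v))
  ry <- drop(proj(y))
  rG <- proj(G)
  gss <- colSums(rG^2)
  degenerate <- gss < n * 1e-12
  gss_safe <- ifelse(degenerate, 1, gss)
  beta <- colSums(rG * ry) / gss_safe
  rss <- sum(ry^2) - beta^2 * gss_safe
  df <- n - p - 1L
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 / gss_safe)
  beta[degenerate] <- 0
  se[degenerate] <- Inf
  pval <- ifelse(degenerate, 1, z_pvalue(beta / se))
  list(beta = beta, se = se, pval = pval, degenerate = degenerate)
}

scan_logistic <- function(y, G, X) {
  nv <- ncol(G)
  beta <- se <- numeric(nv)
  degenerate <- logical(nv)
  for (j in seq_len(nv)) {
    g <- G[, j]
    if (stats::var(g) == 0) {
      degenerate[j] <- TRUE
      beta[j] <- 0; se[j] <- Inf
      next
    }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(X, g), y, family = stats::binomial())
    )
    k <- ncol(X) + 1L
    cf <- fit$coefficients[k]
    # observed-information se from the weighted cross-product
    W <- fit$weights
    XtWX <- crossprod(cbind(X, g) * sqrt(W))
    v <- tryCatch(solve(XtWX)[k, k], error = function(e) Inf)
    beta[j] <- cf
    se[j] <- sqrt(v)
  }
  pval <- ifelse(degenerate, 1, z_pvalue(beta / se))
  list(beta = beta, se = se, pval = pval, degenerate = degenerate)
}

#' Subset a cohort by a phenotype condition
#'
#' Convenience filter used for sex-stratified scans
#' (e.g. `filter_cohort(ch, sex == 1)`).
#'
#' @param cohort A cohort.
#' @param condition Expression evaluated in `cohort$phenotypes`.
#' @return The filtered cohort.
#' @export
filter_cohort <- function(cohort, condition) {
  keep <- eval(substitute(condition), cohort$phenotypes, parent.frame())
  if (!is.logical(keep) || length(keep) != nrow(cohort$phenotypes))
    input_error("condition must evaluate to a logical vector over individuals")
  keep[is.na(keep)] <- FALSE
  cohort$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  cohort$phenotypes <- cohort$phenotypes[keep, , drop = FALSE]
  cohort
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 694)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  alpha <- check_number(alpha, "alpha", 0, 1, open_lower = TRUE)
  n_tests <- check_count(n_tests, "n_tests", min = 1L)
  alpha / n_tests
}

#' Stacked variant-by-time interaction scan
#'
#' Tests, per variant, whether its effect on body-size category differs
#' between early life and adulthood. Each individual contributes two stacked
#' rows (their early and adult category measurements); the model per variant
#' is `category ~ dosage + time + dosage:time + covariates`, with time coded
#' 0 = early, 1 = adult, so the interaction coefficient is the adult effect
#' minus the early effect. Only individuals with both measurements enter
#' (simulated cohorts always have both). Standard errors for the interaction
#' term are cluster-robust by individual, since the two rows of one person
#' are correlated; plain OLS errors are available via
#' `cluster_robust = FALSE` for comparison.
#'
#' Interaction p-values are compared against the Bonferroni threshold
#' `alpha / n_variants_tested`; a variant is flagged `stronger-early` when
#' significant with a negative interaction (larger early effect),
#' `stronger-adult` when positive, otherwise `no-difference`.
#'
#' @param cohort A cohort with both `early_reported` and `adult_category`.
#' @param covariates Covariates entered in the stacked model (default age
#'   and sex; time is always included).
#' @param variants Optional variant-id subset.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param cluster_robust Use cluster-robust (by individual) interaction
#'   standard errors (default) or plain OLS.
#' @return Data frame of class `interaction_result`: `SNP`, `beta_main`
#'   (early-life effect), `beta_interaction`, `se_interaction`,
#'   `pval_interaction`, `flag`.
#' @export
stacked_interaction_scan <- function(cohort, covariates = c("age", "sex"),
                                     variants = NULL, alpha = 0.05,
                                     cluster_robust = TRUE) {
  ph <- cohort$phenotypes
  for (col in c("early_reported", "adult_category"))
    if (!col %in% names(ph) || anyNA(ph[[col]]))
      input_error(paste0("only individuals with measures at both time points ",
                         "can be stacked: '%s' is missing or incomplete"), col)
  G <- cohort$genotypes
  if (!is.null(variants)) {
    missing_v <- setdiff(variants, colnames(G))
    if (length(missing_v))
      input_error("variant(s) not in cohort: %s", paste(missing_v, collapse = ", "))
    G <- G[, variants, drop = FALSE]
  }
  n <- nrow(ph)
  y <- c(as.numeric(ph$early_reported), as.numeric(ph$adult_category))
  time <- rep(c(0, 1), each = n)
  id <- rep(seq_len(n), 2L)
  Xcov <- as.matrix(ph[covariates])
  Xcommon <- cbind(intercept = 1, time = time,
                   Xcov[rep(seq_len(n), 2L), , drop = FALSE])
  nv <- ncol(G)
  k <- ncol(Xcommon) + 2L
  X <- cbind(Xcommon, g = 0, gxt = 0)
  beta_main <- beta_int <- se_int <- numeric(nv)
  for (j in seq_len(nv)) {
    g2 <- rep(G[, j], 2L)
    X[, k - 1L] <- g2
    X[, k] <- g2 * time
    XtX <- crossprod(X)
    bread <- tryCatch(solve(XtX), error = function(e) NULL)
    if (is.null(bread)) {
      beta_main[j] <- 0; beta_int[j] <- 0; se_int[j] <- Inf
      next
    }
    b <- drop(bread %*% crossprod(X, y))
    e <- y - drop(X %*% b)
    if (cluster_robust) {
      S <- rowsum(X * e, id)            # per-individual score sums
      meat <- crossprod(S)
      V <- bread %*% meat %*% bread * n / (n - 1)
    } else {
      V <- bread * sum(e^2) / (2 * n - k)
    }
    beta_main[j] <- b[k - 1L]
    beta_int[j] <- b[k]
    se_int[j] <- sqrt(V[k, k])
  }
  pval <- ifelse(is.finite(se_int), z_pvalue(beta_int / se_int), 1)
  thr <- bonferroni_threshold(alpha, nv)
  # beta_main is the early-life effect, beta_main + beta_int the adult one;
  # "stronger" compares their magnitudes among significant interactions
  adult_eff <- beta_main + beta_int
  flag <- rep("no-difference", nv)
  flag[pval < thr & abs(beta_main) > abs(adult_eff)] <- "stronger-early"
  flag[pval < thr & abs(beta_main) < abs(adult_eff)] <- "stronger-adult"
  out <- data.frame(SNP = colnames(G), beta_main = beta_main,
                    beta_interaction = beta_int, se_interaction = se_int,
                    pval_interaction = pval, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_result", "data.frame")
  attr(out, "threshold") <- thr
  out
}
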