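# Independent oracles used to check the estimators. These deliberately take
# different computational routes (lm/glm fits, naive loops) from the package
# implementations.

# weighted least squares of by on bx through the origin, via lm
oracle_ivw <- function(bx, by, sey) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sey^2)
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)),
       se_fixed = unname(s$coefficients[1, 2] / s$sigma))
}

# weighted normal equations for k exposures, via lm
oracle_mvmr <- function(BX, by, sey) {
  fit <- stats::lm(by ~ 0 + BX, weights = 1 / sey^2)
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)),
       se_fixed = unname(s$coefficients[, 2] / s$sigma))
}

# naive greedy clumping written as an explicit while loop over a candidate
# data frame (no vectorised trickery shared with the implementation)
oracle_clump <- function(stats, G, p_threshold, r2_threshold) {
  cand <- stats[stats$pval < p_threshold, , drop = FALSE]
  kept <- character()
  while (nrow(cand) > 0L) {
    ord <- order(cand$pval, cand$SNP)
    idx <- cand$SNP[ord[1]]
    kept <- c(kept, idx)
    remaining <- setdiff(cand$SNP, idx)
    drop <- vapply(remaining, function(s) {
      suppressWarnings(r <- stats::cor(G[, idx], G[, s]))
      !is.na(r) && r^2 >= r2_threshold
    }, logical(1))
    cand <- cand[cand$SNP %in% remaining[!drop], , drop = FALSE]
  }
  stats[match(kept, stats$SNP), , drop = FALSE]
}

# brute-force per-variant regression scan via lm
oracle_scan <- function(cohort, phenotype, covariates = character()) {
  ph <- cohort$phenotypes
  y <- as.numeric(ph[[phenotype]])
  t(vapply(colnames(cohort$genotypes), function(v) {
    dat <- data.frame(y = y, g = cohort$genotypes[, v], ph[covariates])
    cf <- summary(stats::lm(y ~ ., data = dat))$coefficients
    cf["g", 1:2]
  }, numeric(2)))
}

# a harmonized_set assembled directly from summary-level vectors, for
# estimator tests that do not need the simulation machinery
make_harmonized <- function(bx, by, sey, sex = NULL, labels = NULL) {
  if (is.vector(bx)) bx <- matrix(bx, ncol = 1)
  k <- ncol(bx)
  if (is.null(labels)) labels <- paste0("exposure", seq_len(k))
  if (is.null(sex)) sex <- matrix(0.01, nrow(bx), k)
  if (is.vector(sex)) sex <- matrix(sex, ncol = k)
  n <- nrow(bx)
  dat <- data.frame(SNP = sprintf("rs%05d", seq_len(n)),
                    effect_allele = "A", other_allele = "G",
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    dat[[paste0("beta_x_", labels[i])]] <- bx[, i]
    dat[[paste0("se_x_", labels[i])]] <- sex[, i]
    dat[[paste0("eaf_x_", labels[i])]] <- 0.3
  }
  dat$beta_y <- by
  dat$se_y <- sey
  dat$eaf_y <- 0.3
  dat$action <- "aligned"
  structure(list(data = dat, exposures = labels,
                 drops = data.frame(SNP = character(), reason = character()),
                 palindrome_policy = "frequency",
                 palindrome_window = c(0.42, 0.58)),
            class = "harmonized_set")
}

# sumstats data frame from raw vectors (p-values consistent with beta/se)
make_sumstats <- function(beta, se, snp = sprintf("rs%05d", seq_along(beta)),
                          ea = "A", oa = "G", eaf = 0.3, n = 1000) {
  out <- data.frame(SNP = snp, effect_allele = ea, other_allele = oa,
                    eaf = eaf, beta = beta, se = se,
                    pval = 2 * stats::pnorm(-abs(beta / se)),
                    samplesize = n, stringsAsFactors = FALSE)
  class(out) <- c("sumstats", "data.frame")
  out
}

# hand-built cohort around an explicit genotype matrix
make_cohort <- function(G, phenotypes = NULL) {
  colnames(G) <- sprintf("rs%05d", seq_len(ncol(G)))
  if (is.null(phenotypes))
    phenotypes <- data.frame(id = seq_len(nrow(G)),
                             age = 50, sex = 0, month_of_birth = 1)
  structure(list(genotypes = G, phenotypes = phenotypes,
                 variants = data.frame(SNP = colnames(G),
                                       effect_allele = "A",
                                       other_allele = "G",
                                       maf = colMeans(G) / 2,
                                       block = 1L, class = "null",
                                       beta_early = 0, beta_adult = 0,
                                       stringsAsFactors = FALSE),
                 sample_label = "exposure", outcome_model = "continuous",
                 seed = 0L),
            class = "cohort")
}

# small scenario used across tests; any field can be overridden
tiny_spec <- function(...) {
  args <- list(n_variants = 30L, n_early_variants = 8L, n_adult_variants = 8L,
               n_shared_variants = 0L, effect_size_sd_early = 0.25,
               effect_size_sd_adult = 0.25)
  args <- utils::modifyList(args, list(...))
  do.call(scenario_spec, args)
}
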