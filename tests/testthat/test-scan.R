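test_that("scan betas and ses match the brute-force lm oracle to 1e-10", {
  spec <- scenario_spec(n_variants = 5, n_early_variants = 2,
                        n_adult_variants = 2, seed = 51)
  ch <- simulate_cohort(simulate_panel(spec), spec, 50)
  for (covs in list(character(), c("age", "sex", "month_of_birth"))) {
    mine <- gwas_scan(ch, "early_category", covs)
    oracle <- oracle_scan(ch, "early_category", covs)
    expect_equal(mine$beta, unname(oracle[, 1]), tolerance = 1e-10)
    expect_equal(mine$se, unname(oracle[, 2]), tolerance = 1e-10)
  }
})

test_that("scan p-values are the two-sided normal tail of beta/se", {
  spec <- tiny_spec(seed = 52)
  ch <- simulate_cohort(simulate_panel(spec), spec, 400)
  st <- gwas_scan(ch, "adult_latent", c("age", "sex"))
  expect_equal(st$pval, 2 * pnorm(-abs(st$beta / st$se)), tolerance = 1e-12)
})

test_that("a phenotype equal to a variant's dosage self-regresses to beta 1", {
  spec <- tiny_spec(seed = 53)
  ch <- simulate_cohort(simulate_panel(spec), spec, 500)
  ch$phenotypes$self <- ch$genotypes[, "rs00003"]
  st <- gwas_scan(ch, "self")
  row <- st[st$SNP == "rs00003", ]
  expect_equal(row$beta, 1, tolerance = 1e-12)
  expect_lt(row$se, 1e-8)
})

test_that("constant genotype columns are reported as degenerate", {
  set.seed(54)
  G <- cbind(rbinom(100, 2, 0.3), 0, rbinom(100, 2, 0.4))
  ch <- make_cohort(G)
  ch$phenotypes$y <- rnorm(100)
  st <- gwas_scan(ch, "y")
  expect_equal(attr(st, "degenerate"), "rs00002")
  expect_equal(st$beta[2], 0)
  expect_equal(st$se[2], Inf)
  expect_equal(st$pval[2], 1)
})

test_that("adding an independent covariate leaves scan betas unchanged within noise", {
  spec <- tiny_spec(seed = 55)
  ch <- simulate_cohort(simulate_panel(spec), spec, 5000)
  plain <- gwas_scan(ch, "early_category")
  adj <- gwas_scan(ch, "early_category", c("age", "month_of_birth"))
  expect_lt(max(abs(plain$beta - adj$beta)), 4 * max(plain$se))
  expect_gt(cor(plain$beta, adj$beta), 0.999)
})

test_that("logistic scan agrees with the glm oracle", {
  spec <- scenario_spec(n_variants = 6, n_early_variants = 3,
                        n_adult_variants = 2, beta_early_direct = 0.3,
                        outcome_model = "binary-logistic", seed = 56)
  ch <- simulate_cohort(simulate_panel(spec), spec, 2000)
  st <- gwas_scan(ch, "outcome", c("age", "sex"), model = "logistic")
  for (j in 1:6) {
    fit <- glm(ch$phenotypes$outcome ~ ch$genotypes[, j] +
                 ch$phenotypes$age + ch$phenotypes$sex, family = binomial())
    cf <- summary(fit)$coefficients[2, ]
    expect_equal(st$beta[j], unname(cf[1]), tolerance = 1e-6)
    expect_equal(st$se[j], unname(cf[2]), tolerance = 1e-4)
  }
})

test_that("bonferroni threshold is exact division", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 500), 1e-4)
  expect_equal(bonferroni_threshold(0.05, 694), 0.05 / 694)
  expect_equal(bonferroni_threshold(0.05, 694), 7.2046e-5, tolerance = 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("stacked interaction scan matches lm + sandwich cluster-robust oracle", {
  skip_if_not_installed("sandwich")
  spec <- tiny_spec(seed = 57, n_variants = 4, n_early_variants = 2,
                    n_adult_variants = 1)
  ch <- simulate_cohort(simulate_panel(spec), spec, 300)
  res <- stacked_interaction_scan(ch)
  ph <- ch$phenotypes
  n <- nrow(ph)
  for (j in 1:4) {
    dat <- data.frame(y = c(ph$early_reported, ph$adult_category),
                      g = rep(ch$genotypes[, j], 2),
                      time = rep(c(0, 1), each = n),
                      age = rep(ph$age, 2), sex = rep(ph$sex, 2),
                      id = rep(seq_len(n), 2))
    fit <- lm(y ~ time + age + sex + g + g:time, data = dat)
    expect_equal(res$beta_main[j], unname(coef(fit)["g"]), tolerance = 1e-10)
    expect_equal(res$beta_interaction[j], unname(coef(fit)["time:g"]),
                 tolerance = 1e-10)
    V <- sandwich::vcovCL(fit, cluster = dat$id, type = "HC0", cadjust = TRUE)
    expect_equal(res$se_interaction[j], sqrt(V["time:g", "time:g"]),
                 tolerance = 1e-8)
  }
})

test_that("stacked scan rejects cohorts with missing measurements", {
  spec <- tiny_spec(seed = 58)
  ch <- simulate_cohort(simulate_panel(spec), spec, 100)
  ch$phenotypes$adult_category[5] <- NA
  expect_error(stacked_interaction_scan(ch), "both time points")
})

test_that("interaction coding is adult minus early and detects early-only effects", {
  # no mediation, so early-effect variants have no adult-category effect:
  # their interaction coefficient equals minus the early-category effect
  spec <- scenario_spec(n_variants = 12, n_early_variants = 4,
                        n_adult_variants = 4, beta_early_to_adult = 0,
                        effect_size_sd_early = 0.25,
                        effect_size_sd_adult = 0.25, seed = 59)
  panel <- simulate_panel(spec)
  ch <- simulate_cohort(panel, spec, 20000)
  res <- stacked_interaction_scan(ch)
  early_scan <- gwas_scan(ch, "early_reported", c("age", "sex"))
  early_idx <- panel$variants$class == "early"
  expect_lt(max(abs(res$beta_interaction[early_idx] +
                      early_scan$beta[early_idx])),
            4 * max(res$se_interaction))
  # the strongest early-only variant is flagged stronger-early
  strongest <- which(early_idx)[which.max(abs(panel$variants$beta_early[early_idx]))]
  expect_equal(res$flag[strongest], "stronger-early")
  # adult-only variants flag stronger-adult or stay unflagged, never the reverse
  expect_false(any(res$flag[panel$variants$class == "adult"] == "stronger-early"))
})

test_that("sex-stratified scans run on filtered cohorts", {
  spec <- tiny_spec(seed = 60)
  ch <- simulate_cohort(simulate_panel(spec), spec, 1000)
  women <- filter_cohort(ch, sex == 1)
  expect_true(all(women$phenotypes$sex == 1))
  expect_equal(nrow(women$genotypes), sum(ch$phenotypes$sex == 1))
  st <- gwas_scan(women, "early_reported", c("age", "month_of_birth"))
  expect_equal(unique(st$samplesize), nrow(women$phenotypes))
})
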