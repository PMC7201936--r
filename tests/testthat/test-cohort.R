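test_that("category marginals match the configured proportions within binomial bounds", {
  props <- c(0.25, 0.5, 0.25)
  spec <- tiny_spec(category_proportions = props, seed = 31)
  ch <- simulate_cohort(simulate_panel(spec), spec, 4000)
  for (trait in c("early_category", "adult_category")) {
    counts <- tabulate(ch$phenotypes[[trait]] + 1L, 3L)
    for (k in 1:3) {
      bound <- 2.58 * sqrt(4000 * props[k] * (1 - props[k]))  # 99% binomial
      expect_lt(abs(counts[k] - 4000 * props[k]), bound + 1)
    }
  }
})

test_that("path model: outcome-on-early-latent regression recovers the path product", {
  spec <- scenario_spec(n_variants = 50, n_early_variants = 15,
                        n_adult_variants = 15,
                        beta_early_to_adult = 0.6, beta_adult_direct = 0.5,
                        beta_early_direct = 0,
                        confounder_loading_early = 0,
                        confounder_loading_adult = 0,
                        confounder_loading_outcome = 0, seed = 32)
  ch <- simulate_cohort(simulate_panel(spec), spec, 100000)
  fit <- lm(outcome ~ early_latent, data = ch$phenotypes)
  slope <- coef(fit)[["early_latent"]]
  se <- summary(fit)$coefficients["early_latent", 2]
  expect_lt(abs(slope - 0.6 * 0.5), 3 * se)
})

test_that("menarche depends on the early latent only", {
  spec <- tiny_spec(seed = 33, menarche_beta_early = -0.5)
  ch <- simulate_cohort(simulate_panel(spec), spec, 50000)
  fit <- summary(lm(menarche ~ early_latent + adult_latent,
                    data = ch$phenotypes))$coefficients
  expect_lt(abs(fit["early_latent", 1] - (-0.5)), 3 * fit["early_latent", 2])
  expect_lt(abs(fit["adult_latent", 1]), 3 * fit["adult_latent", 2])
})

test_that("exposure and outcome samples are independent draws", {
  spec <- tiny_spec(seed = 34)
  panel <- simulate_panel(spec)
  exp_s <- simulate_cohort(panel, spec, 1000, "exposure")
  out_s <- simulate_cohort(panel, spec, 1000, "outcome")
  expect_false(any(exp_s$phenotypes$id %in% out_s$phenotypes$id))
  r <- cor(exp_s$genotypes[, 1], out_s$genotypes[, 1])
  expect_lt(abs(r), 0.1)
  expect_false(identical(exp_s$genotypes, out_s$genotypes))
})

test_that("binary outcomes follow the logistic model at the configured prevalence", {
  spec <- scenario_spec(n_variants = 20, n_early_variants = 5,
                        n_adult_variants = 5,
                        beta_early_direct = 0, beta_adult_direct = 0,
                        confounder_loading_outcome = 0,
                        outcome_model = "binary-logistic",
                        baseline_prevalence = 0.2, seed = 35)
  ch <- simulate_cohort(simulate_panel(spec), spec, 20000)
  expect_true(all(ch$phenotypes$outcome %in% 0:1))
  expect_lt(abs(mean(ch$phenotypes$outcome) - 0.2), 0.01)
})

test_that("misclassification mode none is the identity", {
  spec <- tiny_spec(seed = 36)
  ch <- simulate_cohort(simulate_panel(spec), spec, 500)
  ch2 <- apply_misclassification(ch, misclass_model("none"))
  expect_identical(ch2$phenotypes$early_reported, ch2$phenotypes$early_category)
})

test_that("nondifferential misclassification follows the confusion matrix and attenuates scan effects", {
  spec <- tiny_spec(seed = 37, n_variants = 60, n_early_variants = 25,
                    effect_size_sd_early = 0.3)
  ch <- simulate_cohort(simulate_panel(spec), spec, 20000)
  cm <- symmetric_confusion(0.2)
  chm <- apply_misclassification(ch, misclass_model("nondifferential", cm))
  # empirical confusion rows match the model
  emp <- prop.table(table(chm$phenotypes$early_category,
                          chm$phenotypes$early_reported), 1)
  expect_lt(max(abs(emp - cm)), 0.02)
  # paired scans: reported-category betas attenuated versus true-category
  true_scan <- gwas_scan(ch, "early_category")
  rep_scan <- gwas_scan(chm, "early_reported")
  strong <- which(true_scan$pval < 1e-8)
  expect_gt(length(strong), 3)
  ratio <- sum(rep_scan$beta[strong] * true_scan$beta[strong]) /
    sum(true_scan$beta[strong]^2)
  expect_lt(ratio, 0.95)
  expect_gt(ratio, 0.4)
})

test_that("differential misclassification shifts reporting upwards with adult size", {
  spec <- tiny_spec(seed = 38)
  ch <- simulate_cohort(simulate_panel(spec), spec, 30000)
  chm <- apply_misclassification(
    ch, misclass_model("differential-on-adult", symmetric_confusion(0.2),
                       adult_dependence_slope = 0.5))
  ph <- chm$phenotypes
  for (true_cat in 0:2) {
    sel <- ph$early_category == true_cat
    hi <- sel & ph$adult_latent > median(ph$adult_latent)
    lo <- sel & !hi
    expect_gt(mean(ph$early_reported[hi]), mean(ph$early_reported[lo]))
  }
})

test_that("cohorts round-trip through their TSV representation", {
  spec <- tiny_spec(seed = 39)
  ch <- simulate_cohort(simulate_panel(spec), spec, 50)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir, "exposure")
  expect_equal(back$genotypes, ch$genotypes)
  expect_equal(back$phenotypes$early_category, ch$phenotypes$early_category)
  expect_equal(back$phenotypes$outcome, ch$phenotypes$outcome, tolerance = 1e-12)
  st1 <- gwas_scan(ch, "adult_latent", c("age", "sex"))
  st2 <- gwas_scan(back, "adult_latent", c("age", "sex"))
  expect_equal(st1$beta, st2$beta, tolerance = 1e-10)
})
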