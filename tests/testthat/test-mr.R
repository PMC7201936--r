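test_that("Wald ratio is the outcome/exposure quotient with delta-method se", {
  wr <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(wr$beta, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratio(1, 0.1, 0, 0.03)$beta, 0)
  expect_equal(wald_ratio(1, 0.1, 0, 0.03)$se, 0.03)
  neg <- wald_ratio(-0.1, 0.01, 0.05, 0.01)
  expect_equal(neg$beta, -0.5)
  expect_gt(neg$se, 0)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01), "zero exposure")
  wr2 <- wald_ratio(0.1, 0.02, 0.05, 0.01, second_order = TRUE)
  expect_gt(wr2$se, wr$se)
})

test_that("IVW reproduces the frozen two-variant normal-equations result", {
  # w = c(1e4, 2500); sum(w bx by) = 100, sum(w bx^2) = 200
  h <- make_harmonized(bx = c(0.1, 0.2), by = c(0.06, 0.08),
                       sey = c(0.01, 0.02))
  fit <- mr_ivw(h)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$se, sqrt(1 / 200), tolerance = 1e-12)
  expect_equal(fit$se, 0.0707, tolerance = 1e-3)
})

test_that("IVW equals the weighted-regression-through-origin oracle to 1e-10", {
  set.seed(81)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    bx <- rnorm(n, 0.1, 0.05)
    sey <- runif(n, 0.005, 0.05)
    by <- 0.4 * bx + rnorm(n, 0, sey)
    h <- make_harmonized(bx, by, sey)
    fit <- mr_ivw(h)
    oracle <- oracle_ivw(bx, by, sey)
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se_fixed, tolerance = 1e-10)
  }
})

test_that("identical Wald ratios give the ratio exactly with zero heterogeneity", {
  h <- make_harmonized(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.1, 0.15),
                       sey = c(0.01, 0.03, 0.02))
  fit <- mr_ivw(h)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$Q, 0, tolerance = 1e-20)
  expect_error(mr_ivw(make_harmonized(0.1, 0.05, 0.01)), "wald_ratio")
})

test_that("CI and OR transforms follow the 1.96-normal convention", {
  h <- make_harmonized(bx = c(0.1, 0.2), by = c(0.06, 0.08),
                       sey = c(0.01, 0.02))
  fit <- mr_ivw(h)
  expect_equal(fit$ci_lower, fit$beta - 1.96 * fit$se)
  expect_equal(fit$ci_upper, fit$beta + 1.96 * fit$se)
  expect_equal(fit$or, exp(fit$beta))
  expect_equal(fit$or_ci_lower, exp(fit$ci_lower))
  expect_equal(fit$or_ci_upper, exp(fit$ci_upper))
})

test_that("random-effects IVW inflates the se only under heterogeneity", {
  set.seed(82)
  bx <- rnorm(20, 0.1, 0.03)
  sey <- rep(0.01, 20)
  by <- 0.4 * bx + rnorm(20, 0, 0.05)  # extra-weight heterogeneity
  h <- make_harmonized(bx, by, sey)
  fe <- mr_ivw(h)
  re <- mr_ivw(h, random_effects = TRUE)
  expect_gt(fe$Q / fe$Q_df, 1)
  expect_equal(re$beta, fe$beta)
  expect_equal(re$se, fe$se * sqrt(fe$Q / fe$Q_df), tolerance = 1e-12)
})

test_that("MR-Egger recovers a directional pleiotropy offset", {
  set.seed(83)
  n <- 200
  bx <- abs(rnorm(n, 0.12, 0.05))
  sey <- runif(n, 0.01, 0.02)
  by <- 0.02 + 0.4 * bx + rnorm(n, 0, sey)  # intercept 0.02, slope 0.4
  h <- make_harmonized(bx, by, sey)
  fit <- mr_egger(h)
  expect_lt(abs(fit$egger_intercept - 0.02), 3 * fit$egger_intercept_se)
  expect_lt(abs(fit$beta - 0.4), 3 * fit$se)
  expect_equal(fit$Q_df, n - 2)
  expect_error(mr_egger(make_harmonized(c(0.1, 0.2), c(0.05, 0.1),
                                        c(0.01, 0.01))), ">= 3")
})

test_that("Egger orientation makes the fit invariant to exposure sign flips", {
  set.seed(84)
  bx <- rnorm(50, 0, 0.1)
  sey <- rep(0.01, 50)
  by <- 0.3 * bx + rnorm(50, 0, sey)
  h1 <- make_harmonized(bx, by, sey)
  h2 <- make_harmonized(-bx, -by, sey)
  expect_equal(mr_egger(h1)$beta, mr_egger(h2)$beta, tolerance = 1e-12)
})

test_that("Egger intercept is calibrated under no pleiotropy", {
  set.seed(85)
  hits <- 0L
  reps <- 300L
  for (r in seq_len(reps)) {
    bx <- abs(rnorm(30, 0.12, 0.04))
    sey <- rep(0.01, 30)
    by <- 0.4 * bx + rnorm(30, 0, sey)
    fit <- mr_egger(make_harmonized(bx, by, sey))
    if (abs(fit$egger_intercept) > 1.96 * fit$egger_intercept_se)
      hits <- hits + 1L
  }
  # nominal 5% rejection within a 99% binomial band
  expect_lt(abs(hits / reps - 0.05), 2.58 * sqrt(0.05 * 0.95 / reps) + 0.001)
})

test_that("Cochran's Q is zero for proportional effects and chi-square under homogeneity", {
  h <- make_harmonized(bx = c(0.1, 0.2, 0.4), by = c(0.03, 0.06, 0.12),
                       sey = c(0.01, 0.02, 0.01))
  fit <- mr_ivw(h)
  q <- cochran_q(h, fit)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$df, 2)
  set.seed(86)
  qs <- replicate(400, {
    bx <- rnorm(25, 0.1, 0.03)
    sey <- runif(25, 0.01, 0.03)
    by <- 0.4 * bx + rnorm(25, 0, sey)
    h <- make_harmonized(bx, by, sey)
    cochran_q(h, mr_ivw(h))$Q
  })
  expect_lt(abs(mean(qs) / 24 - 1), 0.05)
  frac <- mean(qs > qchisq(0.95, 24))
  expect_lt(abs(frac - 0.05), 2.58 * sqrt(0.05 * 0.95 / 400) + 0.001)
})

test_that("Q errors on mismatched fits and single variants", {
  h <- make_harmonized(bx = c(0.1, 0.2), by = c(0.05, 0.1), sey = c(0.01, 0.01))
  fit <- mr_ivw(h)
  h2 <- make_harmonized(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.1, 0.2),
                        sey = c(0.01, 0.01, 0.01))
  expect_error(cochran_q(h2, fit), "variants")
})

test_that("mean F is the average squared z statistic", {
  st <- make_sumstats(beta = c(1), se = c(0.1))
  expect_equal(mean_f(st), 100)
  st2 <- make_sumstats(beta = c(0.5, 1), se = c(0.1, 0.1))
  expect_equal(mean_f(st2), 62.5)
  expect_error(mean_f(make_sumstats(0.1, 0.01)[0, ]), "empty")
})

test_that("null instruments have mean F near one", {
  spec <- scenario_spec(n_variants = 400, n_early_variants = 0,
                        n_adult_variants = 0, seed = 87)
  ch <- simulate_cohort(simulate_panel(spec), spec, 2000)
  st <- gwas_scan(ch, "early_category", c("age", "sex"))
  expect_lt(abs(mean_f(st) - 1), 3 * sqrt(2 / 400))
})

test_that("odds-ratio transform matches direct evaluation", {
  expect_equal(to_odds_ratio(0, 0.1)$or, 1)
  degenerate <- to_odds_ratio(log(2), 0)
  expect_equal(degenerate$or, 2)
  expect_equal(degenerate$ci_lower, 2)
  x <- to_odds_ratio(0.399, 0.060)
  expect_equal(x$or, exp(0.399), tolerance = 1e-12)
  expect_equal(x$ci_lower, exp(0.399 - 1.96 * 0.060), tolerance = 1e-12)
  expect_equal(x$ci_upper, exp(0.399 + 1.96 * 0.060), tolerance = 1e-12)
  expect_equal(round(x$or, 2), 1.49)
})
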