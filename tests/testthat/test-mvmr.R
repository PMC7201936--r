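test_that("separable instruments give a diagonal system solved exactly", {
  bx <- rbind(c(0.1, 0), c(0, 0.1))
  h <- make_harmonized(bx, by = c(0.05, 0.02), sey = c(0.01, 0.01),
                       labels = c("early", "adult"))
  h$data <- rbind(h$data, h$data)  # 4 variants > k
  h$data$SNP <- sprintf("rs%05d", 1:4)
  fit <- mvmr_fit(h)
  expect_equal(unname(fit$beta), c(0.5, 0.2), tolerance = 1e-12)
})

test_that("k = 1 multivariable fit reduces to the univariable IVW fit", {
  set.seed(91)
  bx <- rnorm(15, 0.1, 0.04)
  sey <- runif(15, 0.01, 0.03)
  by <- 0.4 * bx + rnorm(15, 0, sey)
  h <- make_harmonized(bx, by, sey, labels = "early")
  uni <- mr_ivw(h)
  multi <- mvmr_fit(h)
  expect_equal(unname(multi$beta), uni$beta, tolerance = 1e-10)
  expect_equal(unname(multi$se), uni$se, tolerance = 1e-10)
  expect_equal(multi$Q, uni$Q, tolerance = 1e-10)
})

test_that("dense designs match the weighted normal-equations oracle to 1e-10", {
  set.seed(92)
  for (k in 2:3) {
    BX <- matrix(rnorm(20 * k, 0.08, 0.05), 20, k)
    sey <- runif(20, 0.01, 0.03)
    theta <- c(0.5, -0.2, 0.3)[seq_len(k)]
    by <- drop(BX %*% theta) + rnorm(20, 0, sey)
    h <- make_harmonized(BX, by, sey)
    fit <- mvmr_fit(h)
    oracle <- oracle_mvmr(BX, by, sey)
    expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-10)
    expect_equal(unname(fit$se), oracle$se_fixed, tolerance = 1e-10)
    expect_equal(fit$Q_df, 20 - k)
  }
})

test_that("degenerate designs raise informative errors", {
  set.seed(93)
  bx <- rnorm(10, 0.1, 0.04)
  h_dup <- make_harmonized(cbind(bx, bx), by = 0.4 * bx,
                           sey = rep(0.01, 10),
                           labels = c("early", "adult"))
  expect_error(mvmr_fit(h_dup), "early ~ adult")
  h_small <- make_harmonized(matrix(c(0.1, 0, 0, 0.1), 2), by = c(0.05, 0.02),
                             sey = c(0.01, 0.01))
  expect_error(mvmr_fit(h_small), "more variants than exposures")
})

test_that("conditional F approaches the marginal F for orthogonal exposures and 0 for duplicates", {
  set.seed(94)
  n <- 60
  bx1 <- c(rnorm(n / 2, 0.2, 0.02), rep(0, n / 2))
  bx2 <- c(rep(0, n / 2), rnorm(n / 2, 0.2, 0.02))
  sex <- matrix(0.02, n, 2)
  h <- make_harmonized(cbind(bx1, bx2), by = rnorm(n, 0, 0.01),
                       sey = rep(0.01, n), sex = sex,
                       labels = c("early", "adult"))
  marginal <- mean((bx1 / 0.02)^2)
  cf <- conditional_f(h, "early")
  expect_gt(cf, 0.5 * marginal)
  expect_lt(cf, 1.5 * marginal)
  h_dup <- make_harmonized(cbind(bx1, bx1), by = rnorm(n, 0, 0.01),
                           sey = rep(0.01, n), sex = sex,
                           labels = c("early", "adult"))
  expect_lt(conditional_f(h_dup, "early"), 1e-10)
  expect_error(conditional_f(make_harmonized(bx1, bx1, rep(0.01, n)),
                             "exposure1"), "mean_f")
})

test_that("a weak collinear exposure has conditional F far below its marginal F", {
  set.seed(95)
  bx1 <- rnorm(40, 0.2, 0.05)
  bx2 <- 0.8 * bx1 + rnorm(40, 0, 0.01)  # mostly shared signal
  sex <- matrix(0.02, 40, 2)
  h <- make_harmonized(cbind(bx1, bx2), by = rnorm(40, 0, 0.01),
                       sey = rep(0.01, 40), sex = sex,
                       labels = c("early", "adult"))
  marginal2 <- mean((bx2 / 0.02)^2)
  expect_lt(conditional_f(h, "adult"), 0.2 * marginal2)
})

test_that("decomposition classifies the mediated pattern seen for cardiometabolic outcomes", {
  # univariable OR 1.49 [1.33, 1.68] vs multivariable OR 1.02 [0.86, 1.22]:
  # total excludes the null, direct covers it
  total <- lifecourseMR:::new_mr_fit("ivw", "early",
                                     beta = log(1.49),
                                     se = (log(1.68) - log(1.33)) / (2 * 1.96),
                                     n_variants = 295)
  direct <- structure(list(exposures = c("early", "adult"),
                           beta = c(early = log(1.02), adult = log(1.82)),
                           se = c(early = (log(1.22) - log(0.86)) / (2 * 1.96),
                                  adult = 0.07),
                           ci_lower = c(early = log(0.86), adult = log(1.59)),
                           ci_upper = c(early = log(1.22), adult = log(2.09)),
                           n_variants = 694),
                      class = "mvmr_fit")
  dec <- decompose_effects(total, direct, "early")
  expect_equal(dec$scenario, "mediated")
  expect_equal(dec$indirect, log(1.49) - log(1.02), tolerance = 1e-12)
  expect_equal(dec$indirect_se,
               sqrt(total$se^2 + direct$se[["early"]]^2), tolerance = 1e-12)
})

test_that("decomposition labels direct-only and mixed patterns", {
  total <- lifecourseMR:::new_mr_fit("ivw", "early", beta = -0.46, se = 0.07,
                                     n_variants = 124)
  direct_same <- structure(list(exposures = "early",
                                beta = c(early = -0.46), se = c(early = 0.08),
                                ci_lower = c(early = -0.46 - 1.96 * 0.08),
                                ci_upper = c(early = -0.46 + 1.96 * 0.08)),
                           class = "mvmr_fit")
  dec <- decompose_effects(total, direct_same, "early")
  expect_equal(dec$scenario, "direct-only")
  expect_equal(dec$indirect, 0)
  direct_half <- structure(list(exposures = "early",
                                beta = c(early = -0.2), se = c(early = 0.03),
                                ci_lower = c(early = -0.2 - 1.96 * 0.03),
                                ci_upper = c(early = -0.2 + 1.96 * 0.03)),
                           class = "mvmr_fit")
  expect_equal(decompose_effects(total, direct_half, "early")$scenario, "both")
})

test_that("negative control passes when only the early path reaches the trait", {
  set.seed(96)
  n <- 40
  e <- c(rnorm(n / 2, 0.15, 0.03), rep(0, n / 2))     # early instrument effects
  a <- c(rep(0, n / 2), rnorm(n / 2, 0.15, 0.03))     # adult-only effects
  bxE <- e + rnorm(n, 0, 0.005)
  bxA <- 0.6 * e + a + rnorm(n, 0, 0.005)
  sey <- rep(0.01, n)
  by_menarche <- -0.9 * e + rnorm(n, 0, sey)          # early path only
  h <- make_harmonized(cbind(bxE, bxA), by_menarche, sey,
                       labels = c("early", "adult"))
  h_early <- make_harmonized(bxE[1:(n / 2)], by_menarche[1:(n / 2)],
                             sey[1:(n / 2)], labels = "early")
  nc <- negative_control_analysis(h, h_early)
  expect_true(nc$adult_null)
  expect_true(nc$early_consistent)
  expect_true(nc$pass)
  # inject an artificial adult path: the report must fail
  by_bad <- -0.9 * e + 0.5 * (0.6 * e + a) + rnorm(n, 0, sey)
  h_bad <- make_harmonized(cbind(bxE, bxA), by_bad, sey,
                           labels = c("early", "adult"))
  nc_bad <- negative_control_analysis(h_bad, h_early)
  expect_false(nc_bad$adult_null)
  expect_false(nc_bad$pass)
})
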