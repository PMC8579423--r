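test_that("Rubin pooling matches the hand-computed oracle", {
  p <- pool_rubin(c(0.1, 0.2, 0.3), c(0.01, 0.01, 0.01))
  expect_equal(p$estimate, 0.2)
  expect_equal(p$W, 0.01)
  expect_equal(p$B, 0.01)
  expect_equal(p$total_var, 0.01 + (4 / 3) * 0.01, tolerance = 1e-12)
  expect_equal(p$se, sqrt(0.0233333333), tolerance = 1e-6)

  one <- pool_rubin(0.5, 0.04)
  expect_equal(one$estimate, 0.5)
  expect_equal(one$total_var, 0.04)

  same <- pool_rubin(rep(0.3, 5), rep(0.02, 5))
  expect_equal(same$B, 0)
  expect_equal(same$total_var, same$W)
})

test_that("pooled total variance never falls below the within variance", {
  set.seed(4)
  for (i in 1:20) {
    m <- sample(2:10, 1)
    p <- pool_rubin(rnorm(m), runif(m, 0.01, 0.1))
    expect_gte(p$total_var, p$W)
  }
})

test_that("minimum detectable effect is monotone and vanishes with n", {
  expect_lt(mdes(200, 200), mdes(100, 100))
  expect_lt(mdes(150, 100), mdes(100, 100))
  expect_lt(mdes(1e7, 1e7), 0.002)
  expect_error(mdes(1, 100), "at least 2")
})

test_that("unadjusted linear fit reproduces the difference in means with HC1 variance", {
  set.seed(11)
  n <- 120
  d <- data.frame(arm = rep(c("modified", "standard"), each = n / 2),
                  sex = sample(c("male", "female"), n, TRUE),
                  y = rnorm(n))
  f <- fit_mean_difference(d, "y", adjusted = FALSE)
  expect_equal(f$estimate,
               mean(d$y[d$arm == "modified"]) -
                 mean(d$y[d$arm == "standard"]),
               tolerance = 1e-12)

  # independent route: lm + sandwich's HC1 estimator
  lmfit <- lm(y ~ I(arm == "modified"), data = d)
  expect_equal(f$se,
               sqrt(sandwich::vcovHC(lmfit, type = "HC1")[2, 2]),
               tolerance = 1e-10)

  d$x <- rnorm(n); d$y2 <- d$y + 0.5 * d$x
  f2 <- fit_mean_difference(d, "y2", adjusted = TRUE, covariates = "x")
  lmfit2 <- lm(y2 ~ I(arm == "modified") + x, data = d)
  expect_equal(f2$estimate, unname(coef(lmfit2)[2]), tolerance = 1e-10)
  expect_equal(f2$se,
               sqrt(sandwich::vcovHC(lmfit2, type = "HC1")[2, 2]),
               tolerance = 1e-10)
})

test_that("a perfectly predicted outcome gives estimate 1 and zero SE", {
  d <- data.frame(arm = rep(c("modified", "standard"), 20))
  d$y <- as.numeric(d$arm == "modified")
  f <- fit_mean_difference(d, "y", adjusted = FALSE)
  expect_equal(f$estimate, 1.0)
  expect_equal(f$se, 0)
})

test_that("sandwich and classical SEs agree under homoscedasticity", {
  set.seed(21)
  ratio <- replicate(40, {
    n <- 300
    d <- data.frame(arm = rep(c("modified", "standard"), n / 2),
                    x = rnorm(n))
    d$y <- 0.2 * d$x + rnorm(n)
    f <- fit_mean_difference(d, "y", adjusted = TRUE, covariates = "x")
    cls <- summary(lm(y ~ I(arm == "modified") + x, d))$coefficients[2, 2]
    f$se / cls
  })
  expect_gt(mean(ratio), 0.9)
  expect_lt(mean(ratio), 1.1)
})

test_that("collinear design columns are dropped with a message", {
  set.seed(31)
  d <- data.frame(arm = rep(c("modified", "standard"), 30),
                  x = rnorm(60))
  d$x2 <- 2 * d$x
  d$y <- rnorm(60)
  expect_message(f <- fit_mean_difference(d, "y", adjusted = TRUE,
                                          covariates = c("x", "x2")),
                 "collinear")
  expect_true(is.finite(f$se))
})

test_that("logistic fit reproduces the 2x2 cross-product odds ratio", {
  d <- data.frame(
    arm = rep(c("modified", "standard"), c(100, 100)),
    y = c(rep(1, 20), rep(0, 80), rep(1, 30), rep(0, 70)))
  f <- fit_odds_ratio(d, "y", adjusted = FALSE)
  expect_equal(f$or, (20 * 70) / (80 * 30), tolerance = 1e-6)
  expect_equal(f$estimate, log((20 * 70) / (80 * 30)), tolerance = 1e-6)

  d0 <- d; d0$y <- 0
  expect_error(fit_odds_ratio(d0, "y", adjusted = FALSE), "degenerate")

  dsep <- d; dsep$y <- as.numeric(dsep$arm == "modified")
  fs <- fit_odds_ratio(dsep, "y", adjusted = FALSE)
  expect_equal(fs$flag, "separation")
  expect_true(is.na(fs$estimate))
  expect_error(fit_odds_ratio(dsep, "y", adjusted = FALSE,
                              on_separation = "error"), "separation")
})

test_that("odds-ratio intervals cover the null at close to nominal rate", {
  set.seed(41)
  covered <- replicate(200, {
    n <- 300
    d <- data.frame(arm = rep(c("modified", "standard"), n / 2))
    d$y <- rbinom(n, 1, 0.3)
    f <- fit_odds_ratio(d, "y", adjusted = FALSE)
    f$ci_low <= 0 && f$ci_high >= 0
  })
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("imputation is the identity on complete data and respects deaths", {
  sim <- iront_sim()
  rows <- sim$dataset[!sim$dataset$death, ]
  complete <- rows[complete.cases(
    rows[, c("maternal_smoking", "maternal_degree", "sd_maths16")]), ]
  mi <- impute_chained(complete, imputation_config(
    m = 5, seed = 1,
    vars = c("maternal_smoking", "maternal_degree", "sd_maths16")))
  expect_length(mi$datasets, 5)
  for (d in mi$datasets) expect_identical(d, complete)
  expect_length(mi$imputed_vars, 0)

  with_death <- sim$dataset
  with_death$death[1] <- TRUE
  expect_error(impute_chained(with_death, imputation_config()),
               "deceased")
  bad <- complete; bad$sd_maths16 <- NA_real_
  expect_error(impute_chained(bad, imputation_config(
    vars = "sd_maths16")), "100% missing")
})

test_that("imputation is deterministic given the seed and completes all values", {
  sim <- iront_sim()
  rows <- sim$dataset[!sim$dataset$death, ]
  cfg <- imputation_config(m = 3, iterations = 5, seed = 77,
                           vars = c("maternal_smoking", "maternal_degree",
                                    "sd_maths16"))
  a <- impute_chained(rows, cfg)
  b <- impute_chained(rows, cfg)
  expect_identical(a$datasets, b$datasets)
  for (d in a$datasets) {
    expect_false(anyNA(d$sd_maths16))
    expect_false(anyNA(d$maternal_smoking))
  }
  # observed values are never altered
  obs <- !is.na(rows$sd_maths16)
  expect_identical(a$datasets[[1]]$sd_maths16[obs], rows$sd_maths16[obs])
})

test_that("MI is unbiased under MCAR missingness in a null-adjacent model", {
  set.seed(51)
  true_eff <- 0.4
  ests <- replicate(200, {
    n <- 150
    d <- data.frame(arm = rep(c("modified", "standard"), n / 2),
                    death = FALSE)
    d$y <- true_eff * (d$arm == "modified") + rnorm(n)
    d$y[runif(n) < 0.2] <- NA
    mi <- impute_chained(d, imputation_config(m = 5, iterations = 5,
                                              seed = sample.int(1e6, 1),
                                              vars = "y"))
    pool_fit(mi, "y", "mean_difference", adjusted = FALSE)$estimate
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - true_eff), 3 * mc_se)
})

test_that("the sensitivity matrix carries five labelled analyses per cell", {
  sim <- iront_sim()
  sm <- run_sensitivity_matrix(sim$dataset,
                               config = imputation_config(m = 3,
                                                          iterations = 5,
                                                          seed = 5))
  expect_setequal(sm$analysis,
                  c("MI_adjusted", "MI_unadjusted", "CC_adjusted",
                    "CC_unadjusted", "external_standardised"))
  expect_equal(nrow(sm), 5)
  est <- sm$estimate[sm$note == ""]
  expect_true(all(is.finite(est)))
  # a null simulation should not produce wildly divergent cells
  expect_lt(max(est) - min(est), 0.5)
})
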