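test_that("unadjusted fit reproduces the 2x2 cross-product odds ratio", {
  # a=20 exposed cases, b=80 exposed non-cases, c=10, d=90 -> OR 2.25
  outcome <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  apd <- c(rep(1, 100), rep(0, 100))
  fit <- fit_logistic(outcome, apd)
  expect_equal(fit$odds_ratio, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_obs, 200)
  expect_lte(fit$ci_low, fit$odds_ratio)
  expect_gte(fit$ci_high, fit$odds_ratio)

  # Wald CI is exactly symmetric on the log scale
  expect_equal(log(fit$ci_high) - log(fit$odds_ratio),
               log(fit$odds_ratio) - log(fit$ci_low), tolerance = 1e-12)

  # likelihood-ratio p is available and close to Wald here
  lr <- fit_logistic(outcome, apd, test = "lr")
  expect_equal(lr$odds_ratio, fit$odds_ratio)
  expect_equal(lr$p_value, fit$p_value, tolerance = 0.3)
})

test_that("estimates are invariant to row order", {
  set.seed(31)
  n <- 2000
  covs <- data.frame(
    age_group = factor(sample(c("65_69", "70_74", "75_79", "GE_80"), n,
                              TRUE),
                       levels = c("65_69", "70_74", "75_79", "GE_80")),
    male = runif(n) < 0.5,
    rx_risk_score = rnorm(n, 1.5, 0.4)
  )
  apd <- as.integer(runif(n) < 0.25)
  y <- as.integer(runif(n) < plogis(-1.5 + 0.7 * apd + 0.2 * covs$male))
  f1 <- fit_logistic(y, apd, covs)
  perm <- sample(n)
  f2 <- fit_logistic(y[perm], apd[perm], covs[perm, ])
  expect_equal(f1$odds_ratio, f2$odds_ratio, tolerance = 1e-10)
  expect_equal(f1$ci_low, f2$ci_low, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)
})

test_that("degenerate inputs are refused or flagged, never silent", {
  expect_error(fit_logistic(rep(1, 50), rep(0:1, 25)), "constant")
  expect_error(fit_logistic(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(fit_logistic(c(0, 1, 2, 1), rep(0:1, 2)), "binary")

  # perfect separation: flagged through converged = FALSE
  y <- c(rep(0, 30), rep(1, 30))
  x <- y
  fit <- fit_logistic(y, x)
  expect_false(fit$converged)
})

test_that("a null cohort gives odds ratios near one across the grid", {
  set.seed(37)
  n <- 6000
  ids <- sprintf("s%04d", 1:n)
  covs <- data.frame(
    patient_id = ids,
    age_group = factor(sample(c("65_69", "70_74", "75_79", "GE_80"), n,
                              TRUE),
                       levels = c("65_69", "70_74", "75_79", "GE_80")),
    male = runif(n) < 0.5,
    race = factor(sample(c("WHITE", "BLACK", "OTHER"), n, TRUE),
                  levels = c("WHITE", "BLACK", "OTHER")),
    region = factor(sample(c("NORTHEAST", "MIDWEST", "SOUTH", "WEST"), n,
                           TRUE),
                    levels = c("NORTHEAST", "MIDWEST", "SOUTH", "WEST")),
    rx_risk_score = rnorm(n, 1.5, 0.4),
    neurologist_visit = runif(n) < 0.7
  )
  profiles <- data.frame(patient_id = ids)
  for (nm in names(synthetic_code_sets())) {
    profiles[[nm]] <- runif(n) < 0.2   # independent of severity
  }
  cls <- data.table::rbindlist(lapply(names(dosing_rules()), function(r) {
    data.frame(patient_id = ids, rule = r, is_apd = runif(n) < 0.2)
  }))
  fits <- fit_all(profiles, cls, covs)
  expect_equal(nrow(fits), 9 * 4)
  expect_true(all(fits$odds_ratio > 0.8 & fits$odds_ratio < 1.25))
  # deterministic re-run
  expect_equal(fits, fit_all(profiles, cls, covs))
})

test_that("descriptives report group percentages, means and tests", {
  n <- 200
  ids <- sprintf("d%03d", 1:n)
  apd <- rep(c(TRUE, FALSE, FALSE, FALSE), 50)
  covs <- data.frame(
    patient_id = ids,
    age_group = factor(rep("70_74", n),
                       levels = c("65_69", "70_74", "75_79", "GE_80")),
    male = c(rep(TRUE, 40), rep(FALSE, 160)),
    race = factor(rep("WHITE", n), levels = c("WHITE", "BLACK", "OTHER")),
    region = factor(rep("SOUTH", n),
                    levels = c("NORTHEAST", "MIDWEST", "SOUTH", "WEST")),
    rx_risk_score = c(rep(1.2, 50), rep(1.6, 150)),
    neurologist_visit = rep(c(TRUE, FALSE), 100)
  )
  cls <- data.frame(patient_id = ids, rule = "LED_GT_1000", is_apd = apd)
  desc <- describe_cohort(covs, cls)

  male_apd <- desc[desc$variable == "sex" & desc$category == "male" &
                     desc$group == "apd", ]
  expect_equal(male_apd$n, sum(covs$male & apd))
  expect_equal(male_apd$pct, claims_pct(sum(covs$male & apd), sum(apd)))
  expect_equal(unique(desc$test[desc$variable == "sex"]), "CHI_SQUARE")

  score <- desc[desc$variable == "rx_risk_score" & desc$group == "overall", ]
  expect_equal(score$mean, mean(covs$rx_risk_score))
  expect_equal(score$test, "T_TEST")

  # identical group compositions: chi-square p ~ 1
  apd2 <- rep(c(TRUE, FALSE), 100)
  covs2 <- covs
  covs2$male <- rep(c(TRUE, TRUE, FALSE, FALSE), 50)  # same split per group
  covs2$neurologist_visit <- covs2$male
  covs2$rx_risk_score <- rep(c(1.1, 1.9), 100)
  desc2 <- describe_cohort(covs2, data.frame(patient_id = ids,
                                             rule = "LED_GT_1000",
                                             is_apd = apd2))
  expect_equal(unique(desc2$p_value[desc2$variable == "sex"]), 1,
               tolerance = 1e-9)

  # single-group input is undefined
  expect_error(describe_cohort(covs, transform(cls, is_apd = TRUE)),
               "one severity group")
})

test_that("the estimator recovers configured odds ratios", {
  # quick calibration at reduced scale; the full-scale run lives in the
  # acceptance suite
  sim <- or_recovery_sim(true_ors = 2.0, n = 5000, n_reps = 20, seed = 99)
  expect_true(all(sim$converged))
  expect_lt(abs(mean(sim$log_or_error)), 0.05)
  expect_gte(mean(sim$ci_covers), 0.8)
})
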