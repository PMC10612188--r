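# helper: quick uncensored/censored Weibull data with one binary covariate
sim_surv <- function(n, shape, lhr = 0, lambda = 0.2, seed = 1,
                     censor_at = Inf) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  E <- -log(runif(n))
  t <- (E * exp(-lhr * x))^(1 / shape) / lambda
  time <- pmin(t, censor_at)
  data.frame(time = time, event = as.integer(t <= censor_at), x = x)
}

test_that("the Newton MLE agrees with survival::survreg", {
  d <- sim_surv(800, shape = 1.4, lhr = log(1.8), seed = 3, censor_at = 6)
  fit <- weibull_aft(survival::Surv(time, event) ~ x, d)
  ref <- survival::survreg(survival::Surv(time, event) ~ x, d,
                           dist = "weibull")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$scale, ref$scale, tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))), unname(sqrt(diag(ref$var))),
               tolerance = 1e-4)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-5)
})

test_that("sigma and intercept recover closed-form truths", {
  # Weibull(shape 2, scale 1): sigma = 1/shape = 0.5
  d <- sim_surv(10000, shape = 2, lambda = 1, seed = 5)
  fit <- weibull_aft(survival::Surv(time, event) ~ 1, d)
  se_s <- sqrt(diag(fit$vcov))[["log(scale)"]] * fit$scale
  expect_lt(abs(fit$scale - 0.5), 3 * se_s)
  # exponential data: sigma = 1 and intercept = log(mean time)
  d1 <- sim_surv(10000, shape = 1, lambda = 0.5, seed = 6)
  f1 <- weibull_aft(survival::Surv(time, event) ~ 1, d1)
  expect_lt(abs(f1$scale - 1), 3 * sqrt(diag(f1$vcov))[["log(scale)"]])
  se_i <- sqrt(diag(f1$vcov))[["(Intercept)"]]
  expect_lt(abs(coef(f1)[["(Intercept)"]] - log(2)), 3 * se_i + 0.02)
})

test_that("information-criterion identities and likelihood nesting hold", {
  d <- sim_surv(500, shape = 1.2, lhr = 0.4, seed = 9, censor_at = 8)
  full <- weibull_aft(survival::Surv(time, event) ~ x, d)
  reduced <- weibull_aft(survival::Surv(time, event) ~ 1, d)
  expect_equal(full$aic, 2 * full$df - 2 * full$loglik)
  expect_equal(full$bic, full$df * log(full$n) - 2 * full$loglik)
  expect_gte(full$loglik, reduced$loglik - 1e-8)
  expect_equal(AIC(full), full$aic)
  expect_equal(BIC(full), full$bic)
  # vcov symmetric positive semi-definite
  expect_equal(full$vcov, t(full$vcov))
  expect_true(all(eigen(full$vcov, symmetric = TRUE)$values > -1e-10))
})

test_that("hazard-ratio conversion follows the Weibull identity", {
  d <- sim_surv(400, shape = 1.3, lhr = 0.5, seed = 2, censor_at = 10)
  fit <- weibull_aft(survival::Surv(time, event) ~ x, d)
  hr <- hazard_ratio(fit, "x")
  expect_equal(hr$hr, exp(-coef(fit)[["x"]] / fit$scale))
  expect_true(hr$ci_low <= hr$hr && hr$hr <= hr$ci_high)
  expect_error(hazard_ratio(fit, "nope"), "unknown term")
  # beta = 0 gives HR 1; beta = -0.5, sigma = 1 gives e^0.5
  fit0 <- fit
  fit0$coefficients[["x"]] <- 0
  expect_equal(hazard_ratio(fit0, "x")$hr, 1)
  fit0$coefficients[["x"]] <- -0.5
  fit0$scale <- 1
  expect_equal(hazard_ratio(fit0, "x")$hr, exp(0.5))
})

test_that("true hazard ratios are recovered within simulation tolerance", {
  d <- sim_surv(10000, shape = 1.5, lhr = log(2), seed = 12, censor_at = 15)
  fit <- weibull_aft(survival::Surv(time, event) ~ x, d)
  hr <- hazard_ratio(fit, "x")
  expect_gt(hr$hr, 1.8)
  expect_lt(hr$hr, 2.2)
})

test_that("likelihood-ratio test matches the chi-square reference", {
  d <- sim_surv(300, shape = 1, lhr = 0, seed = 4, censor_at = 10)
  f <- weibull_aft(survival::Surv(time, event) ~ x, d)
  r <- weibull_aft(survival::Surv(time, event) ~ 1, d)
  out <- lrt(f, r)
  expect_equal(out$df, 1)
  expect_equal(out$p_value,
               pchisq(2 * (f$loglik - r$loglik), 1, lower.tail = FALSE))
  # identical models: statistic 0, p = 1
  same <- lrt(f, f, df = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_error(lrt(r, f, df = 1), "not nested")
  expect_error(lrt(f, r, df = 0), "degrees of freedom")
})

test_that("rank-deficient designs are rejected with the offending column", {
  d <- sim_surv(100, shape = 1, seed = 8, censor_at = 10)
  d$x2 <- d$x * 2
  expect_error(weibull_aft(survival::Surv(time, event) ~ x + x2, d),
               "collinear")
  d$cst <- 5
  expect_error(weibull_aft(survival::Surv(time, event) ~ cst, d),
               "collinear")
})

test_that("hazard ratios are invariant to affine covariate rescaling", {
  p <- cohort_params(n_patients = 1500, seed = 33)
  co <- generate_cohort(p)
  d <- co$patients
  f1 <- weibull_aft(survival::Surv(time_mace, event_mace) ~ arm + age, d)
  d$age <- (d$age - 60) / 10
  f2 <- weibull_aft(survival::Surv(time_mace, event_mace) ~ arm + age, d)
  expect_equal(hazard_ratio(f1, "armintensive")$hr,
               hazard_ratio(f2, "armintensive")$hr, tolerance = 1e-6)
})

test_that("stratified treatment analysis validates its cells", {
  p <- cohort_params(n_patients = 600, seed = 44)
  co <- generate_cohort(p)
  g <- factor(sample(c("low", "medium", "high"), 600, replace = TRUE),
              levels = c("low", "medium", "high"))
  # force an empty cell
  g2 <- g
  g2[co$patients$arm == "intensive" & g2 == "high"] <- "low"
  expect_error(stratified_treatment_hr(co$patients, g2, "mace",
                                       covariates = "age"),
               "empty arm-by-group cell")
  s <- stratified_treatment_hr(co$patients, g, "mace", covariates = "age")
  expect_equal(s$by_group$group, c("low", "medium", "high"))
  expect_true(all(s$by_group$hr > 0))
  expect_true(s$p_interaction >= 0 && s$p_interaction <= 1)
  expect_true(s$p_trend >= 0 && s$p_trend <= 1)
  expect_equal(sum(s$by_group$n), 600)
})
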