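test_that("hinge terms keep the linear predictor continuous at k", {
  d <- kinked_cohort(1500, seed = 61)
  tp <- fit_twopiece(d, outcome = "death", covariates = "age", k = 7.4)
  bb <- coef(tp)[["exposure_below"]]
  ba <- coef(tp)[["exposure_above"]]
  lp <- function(x) bb * pmin(x, 7.4) + ba * pmax(x - 7.4, 0)
  # continuity: the predictor approaches the same value from both sides
  for (eps in c(1e-10, 1e-12))
    expect_lt(max(abs(lp(7.4 + eps) - lp(7.4)),
                  abs(lp(7.4 - eps) - lp(7.4))), 1e-9)
  expect_error(fit_twopiece(d, outcome = "death", covariates = "age",
                            k = 20), "outside")
})

test_that("equal slopes collapse the two-piece model to the line", {
  d <- kinked_cohort(4000, seed = 62, hr_below = 1.3, hr_above = 1.3)
  tp <- fit_twopiece(d, outcome = "death", covariates = character(0),
                     k = 7.5)
  hb <- attr(tp, "hr_below")
  ha <- attr(tp, "hr_above")
  # both slope HRs agree within their joint confidence band
  expect_lt(hb$ci_low, ha$ci_high)
  expect_gt(hb$ci_high, ha$ci_low)
  one <- fit_onepiece(d, outcome = "death", covariates = character(0))
  expect_lt(lrt(tp, one, df = 1)$statistic, 6)
})

test_that("the profile search finds a strongly kinked breakpoint", {
  d <- kinked_cohort(6000, seed = 63)
  tf <- find_inflection(d, outcome = "death", covariates = character(0))
  expect_lt(abs(tf$inflection_k - 7.5), 0.3)
  expect_gte(tf$loglik_twopiece, tf$loglik_onepiece)
  expect_lt(tf$p_curvature, 0.05)
  expect_lt(tf$hr_below$hr, 1)
  expect_gt(tf$hr_above$hr, 1)
  # profile table covers the whole grid
  expect_equal(nrow(tf$profile), length(tf$profile$k))
  expect_true(all(diff(tf$profile$k) > 0))
})

test_that("a single-point grid returns that point", {
  d <- kinked_cohort(800, seed = 64)
  tf <- find_inflection(d, outcome = "death", covariates = character(0),
                        grid = 7.3)
  expect_equal(tf$inflection_k, 7.3)
})

test_that("breakpoint estimate is shift equivariant", {
  d <- kinked_cohort(3000, seed = 65)
  tf1 <- find_inflection(d, outcome = "death", covariates = character(0))
  d2 <- d
  d2$mean_hba1c <- d$mean_hba1c + 1.25
  tf2 <- find_inflection(d2, outcome = "death", covariates = character(0))
  expect_equal(tf2$inflection_k, tf1$inflection_k + 1.25, tolerance = 1e-8)
})

test_that("bootstrap CI is deterministic and validates its inputs", {
  d <- kinked_cohort(1500, seed = 66)
  tf <- find_inflection(d, outcome = "death", covariates = character(0),
                        grid_step = 0.05)
  expect_error(bootstrap_inflection_ci(tf, d, n_boot = 199, seed = 1),
               "at least 200")
  b1 <- bootstrap_inflection_ci(tf, d, n_boot = 200, seed = 5)
  b2 <- bootstrap_inflection_ci(tf, d, n_boot = 200, seed = 5)
  expect_identical(b1$k_ci, b2$k_ci)
  expect_true(b1$k_ci[1] <= b1$inflection_k + 1e-9)
  expect_true(b1$k_ci[2] >= b1$inflection_k - 1e-9)
  expect_lte(b1$n_boot_failed, 40)
})

test_that("curvature LRT is exact for identical likelihoods", {
  d <- kinked_cohort(1000, seed = 67)
  one <- fit_onepiece(d, outcome = "death", covariates = character(0))
  out <- lrt(one, one, df = 1)
  expect_equal(out$p_value, 1)
})
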