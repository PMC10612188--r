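test_that("trajectories are deterministic and respect the zero-noise limit", {
  p <- cohort_params(n_patients = 10)
  p$volatility_mixture <- list(weight = c(0.5, 0.5), shock_sd = c(0, 0.8))
  t1 <- generate_trajectory(p, "intensive", 1, seed = 42)
  t2 <- generate_trajectory(p, "intensive", 1, seed = 42)
  expect_identical(t1, t2)
  # zero shock SD: smooth exponential approach, successive changes shrink
  d <- abs(diff(t1$values))
  expect_lt(max(tail(d, 5)), 0.5)
  # the deterministic curve approaches the arm target
  expect_equal(tail(t1$values, 1), unname(p$arm_targets[["intensive"]]),
               tolerance = 0.01)
  expect_error(generate_trajectory(p, "intensive", 5, seed = 1),
               "unknown volatility stratum: 5")
})

test_that("volatility strata order downstream SD of HbA1c", {
  p <- cohort_params(n_patients = 2000, seed = 15)
  p$volatility_mixture <- list(weight = c(0.5, 0.5), shock_sd = c(0.1, 0.8))
  co <- generate_cohort(p)
  m <- compute_metrics(co$visits)
  by_str <- tapply(m$sd, co$truth$stratum, mean)
  expect_lt(by_str[["1"]], by_str[["2"]])
  expect_gt(by_str[["2"]] - by_str[["1"]], 0.3)
  # HVS separates too
  by_hvs <- tapply(m$hvs, co$truth$stratum, mean)
  expect_lt(by_hvs[["1"]], by_hvs[["2"]])
})

test_that("cohort generation is reproducible and extension-stable", {
  p <- cohort_params(n_patients = 60, seed = 5)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$truth, c2$truth)
  # byte-identical after serialization
  expect_identical(serialize(c1[c("visits", "patients", "truth")], NULL),
                   serialize(c2[c("visits", "patients", "truth")], NULL))
  # adding patients never perturbs existing ones
  c3 <- generate_cohort(cohort_params(n_patients = 90, seed = 5))
  for (cl in c("arm", "age", "time_mace", "event_mace", "time_death"))
    expect_identical(c1$patients[[cl]], c3$patients[[cl]][seq_len(60)])
  expect_identical(c1$truth$mean_hba1c, c3$truth$mean_hba1c[seq_len(60)])
})

test_that("empty cohort and arm-assignment fractions behave", {
  c0 <- generate_cohort(cohort_params(n_patients = 0))
  expect_equal(nrow(c0$patients), 0)
  expect_equal(nrow(c0$visits), 0)
  co <- generate_cohort(cohort_params(n_patients = 2000, seed = 8))
  k <- sum(co$patients$arm == "intensive")
  # binomial 99% bounds around 0.5
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.5)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("Weibull outcome simulation matches closed forms", {
  # shape = 1, baseline hazard lambda = 0.5, no censoring: mean time = 2
  p <- cohort_params(weibull_shape = 1,
                     baseline_log_hazard = c(mace = log(0.5),
                                             death = log(0.5)))
  o <- simulate_outcome(rep(0, 10000), p, seed = 4, censor = FALSE)
  se <- sd(o$time) / sqrt(10000)
  expect_lt(abs(mean(o$time) - 2), 3 * se)
  expect_true(all(o$event == 1))
  # hazard -> 0: everything censored within the administrative window
  o2 <- simulate_outcome(rep(-50, 500), cohort_params(), seed = 4)
  expect_equal(sum(o2$event), 0)
  expect_true(all(o2$time <= cohort_params()$censor_time))
  # true log-HR = log 2: person-year event-rate ratio close to 2
  p1 <- cohort_params(weibull_shape = 1)
  oA <- simulate_outcome(rep(0, 10000), p1, seed = 9)
  oB <- simulate_outcome(rep(log(2), 10000), p1, seed = 10)
  rr <- (sum(oB$event) / sum(oB$time)) / (sum(oA$event) / sum(oA$time))
  expect_lt(abs(rr - 2) / 2, 0.10)
})

test_that("event fraction is monotone in the baseline log hazard", {
  rates <- sapply(c(-4.5, -3.5, -2.5), function(lh) {
    p <- cohort_params(n_patients = 800, seed = 77,
                       baseline_log_hazard = c(mace = lh, death = -4))
    mean(generate_cohort(p)$patients$event_mace)
  })
  expect_true(all(diff(rates) > 0))
})

test_that("parameter validation rejects malformed settings", {
  expect_error(cohort_params(weibull_shape = 0), "weibull_shape")
  expect_error(cohort_params(censor_time = -1), "censor_time")
  expect_error(cohort_params(visit_schedule = c(0, 3, 12)), "4 visits")
  expect_error(cohort_params(visit_schedule = c(0, 2, 2, 6, 12)),
               "strictly increasing")
  expect_error(cohort_params(volatility_mixture = list(weight = c(0.5, 0.4),
                                                       shock_sd = c(0.1, 1))),
               "sum to 1")
})

test_that("cohort files round-trip through write_cohort", {
  co <- generate_cohort(cohort_params(n_patients = 25, seed = 2))
  dir <- file.path(tempdir(), "gv-cohort")
  write_cohort(co, dir)
  v <- read_visits(file.path(dir, "visits.csv"))
  pts <- read_patients(file.path(dir, "patients.csv"))
  expect_equal(nrow(v), nrow(co$visits))
  expect_equal(pts$patient_id, co$patients$patient_id)
  expect_equal(pts$time_mace, co$patients$time_mace, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "params.json")))
  unlink(dir, recursive = TRUE)
})
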