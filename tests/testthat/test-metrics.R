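test_that("HVS matches hand-enumerated successive differences", {
  expect_equal(hvs(c(8, 8, 8)), 0)
  expect_equal(hvs(c(7, 8, 7, 8)), 100)
  # diffs (0.6, -0.1, -0.6): 2 of 3 exceed 0.5
  expect_equal(hvs(c(8, 8.6, 8.5, 7.9)), 200 / 3)
  # strict inequality: a change of exactly 0.5 does not count
  expect_equal(hvs(c(7, 7.5, 8)), 0)
  # measures denominator divides by n instead of n - 1
  expect_equal(hvs(c(8, 8.6, 8.5, 7.9), denominator = "measures"), 50)
  # visits are sorted by time before differencing
  expect_equal(hvs(c(7.9, 8, 8.6, 8.5), times = c(4, 1, 2, 3)), 200 / 3)
})

test_that("SD and mean match hand computation", {
  expect_equal(sd_hba1c(c(8, 8, 8)), 0)
  expect_equal(sd_hba1c(c(7, 8, 9)), 1)
  expect_equal(sd_hba1c(c(6.5, 7.5)), sqrt(0.5^2 * 2 / 1))
  expect_equal(sd_hba1c(c(7, 8, 9), denominator = "n"), sqrt(2 / 3))
  expect_equal(mean_hba1c(8), 8)
  expect_equal(mean_hba1c(c(7, 8, 9)), 8)
  expect_equal(mean_hba1c(c(8, 8.6, 8.5, 7.9)), 8.25)
})

test_that("ineligible trajectories raise errors", {
  expect_error(hvs(7.5), class = "glycvar_ineligible")
  expect_error(sd_hba1c(7.5), class = "glycvar_ineligible")
  expect_error(mean_hba1c(numeric(0)))
  expect_error(hvs(c(7, 8), times = c(1, 1)), "duplicate")
})

test_that("HVS and SD are shift invariant but not scale invariant", {
  set.seed(41)
  for (r in 1:20) {
    v <- rnorm(10, 8, 0.6)
    expect_equal(hvs(v + 1.7), hvs(v))
    expect_equal(sd_hba1c(v + 1.7), sd_hba1c(v))
    expect_false(isTRUE(all.equal(sd_hba1c(v * 2), sd_hba1c(v))))
  }
  # rescaling changes which diffs cross the 0.5 threshold
  v <- c(7, 7.4, 7.8, 8.4)
  expect_false(hvs(v * 2) == hvs(v))
})

test_that("vectorized per-patient metrics equal the naive loop oracle", {
  set.seed(7)
  n_pat <- 300
  visits <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    nv <- sample(2:12, 1)
    data.frame(patient_id = sprintf("P%04d", i), month = sort(sample(0:60, nv)),
               hba1c = round(runif(nv, 5, 12), 2))
  }))
  m <- compute_metrics(visits)
  for (i in sample(n_pat, 60)) {
    v <- visits$hba1c[visits$patient_id == sprintf("P%04d", i)]
    tt <- visits$month[visits$patient_id == sprintf("P%04d", i)]
    v <- v[order(tt)]
    row <- m[m$patient_id == sprintf("P%04d", i), ]
    expect_identical(row$hvs, oracle_hvs(v))
    expect_equal(row$sd, oracle_sd(v))
    expect_equal(row$mean_hba1c, oracle_mean(v))
    expect_equal(row$n_measures, length(v))
  }
})

test_that("VIM exponent fit recovers an exact power law", {
  mm <- data.frame(mean_hba1c = seq(6, 10, length.out = 50))
  mm$sd <- 0.3 * mm$mean_hba1c^1.2
  vm <- suppressWarnings(fit_vim_model(mm))
  expect_equal(vm$exponent_x, 1.2, tolerance = 1e-6)
  expect_equal(vm$fit_r2, 1, tolerance = 1e-9)
  expect_equal(vm$population_mean, mean(mm$mean_hba1c))
})

test_that("VIM exponent is consistent under a null power law", {
  set.seed(11)
  mm <- data.frame(mean_hba1c = runif(2000, 6, 10))
  mm$sd <- exp(rnorm(2000, log(0.6), 0.3))  # independent of the mean
  vm <- fit_vim_model(mm)
  expect_lt(abs(vm$exponent_x), 0.1)
})

test_that("VIM fit degenerate inputs error", {
  expect_error(fit_vim_model(data.frame(mean_hba1c = c(7, 8), sd = c(1, 1))),
               "at least 3")
  expect_error(fit_vim_model(data.frame(mean_hba1c = rep(8, 10),
                                        sd = runif(10, 0.2, 1))),
               "unidentifiable")
})

test_that("VIM formula collapses correctly at x = 0 and x = 1", {
  set.seed(3)
  mm <- data.frame(mean_hba1c = runif(40, 6, 10), sd = runif(40, 0.1, 1.5))
  vm <- structure(list(exponent_x = 0, population_mean = 8.2),
                  class = "vim_model")
  expect_equal(vim(mm, vm), mm$sd)
  vm$exponent_x <- 1
  expect_equal(vim(mm, vm), 8.2 * mm$sd / mm$mean_hba1c)
  vm$exponent_x <- 1.5
  expect_equal(vim(data.frame(sd = 0.8, mean_hba1c = 8), vm),
               0.8 * (8.2 / 8)^1.5)
})

test_that("VIM is decorrelated from the mean where SD is not", {
  set.seed(19)
  n <- 5000
  mm <- data.frame(mean_hba1c = runif(n, 6, 10))
  mm$sd <- 0.25 * mm$mean_hba1c^1.3 * exp(rnorm(n, 0, 0.2))
  vm <- fit_vim_model(mm)
  v <- vim(mm, vm)
  expect_lt(abs(cor(v, mm$mean_hba1c)), 0.05)
  expect_gt(cor(mm$sd, mm$mean_hba1c), 0.3)
})
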