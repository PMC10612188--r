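# Two-piecewise (hinge) exposure modelling: inflection-point search by
# profile likelihood over a breakpoint grid, bootstrap CI, slope hazard
# ratios on either side, and the curvature likelihood-ratio test.

threshold_design <- function(patients, exposure, outcome, covariates) {
  oc <- outcome_cols(outcome)
  need <- c(exposure, oc$time, oc$event, covariates)
  miss <- setdiff(need, names(patients))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  list(oc = oc,
       x = patients[[exposure]],
       fml = function(rhs) as.formula(paste0(
         "survival::Surv(", oc$time, ", ", oc$event, ") ~ ", rhs)))
}

#' One-line (log-linear) exposure model
#'
#' Adjusted Weibull AFT model with the exposure entered linearly; the per-1%
#' hazard ratio is attached.
#'
#' @param patients patient-level data.frame.
#' @param exposure exposure column name (default the per-patient mean HbA1c).
#' @param outcome `"mace"` or `"death"`.
#' @param covariates adjustment covariates.
#' @return a [weibull_aft()] fit with an `hr` attribute ([hazard_ratio()] of
#'   the exposure term).
#' @export
fit_onepiece <- function(patients, exposure = "mean_hba1c",
                         outcome = c("mace", "death"),
                         covariates = default_covariates()) {
  outcome <- match.arg(outcome)
  ds <- threshold_design(patients, exposure, outcome, covariates)
  fit <- weibull_aft(ds$fml(paste(c(exposure, covariates), collapse = " + ")),
                     patients)
  attr(fit, "hr") <- hazard_ratio(fit, exposure)
  fit
}

#' Two-piecewise (hinge) exposure model at a fixed breakpoint
#'
#' Replaces the exposure by the continuous hinge pair `min(x, k)` and
#' `max(x - k, 0)`; the fitted linear predictor is continuous in the exposure
#' at `k` by construction, and each slope converts to a per-1% hazard ratio.
#'
#' @inheritParams fit_onepiece
#' @param k candidate breakpoint, strictly inside the observed exposure
#'   range.
#' @return a [weibull_aft()] fit with attributes `k`, `hr_below`, `hr_above`.
#' @export
fit_twopiece <- function(patients, exposure = "mean_hba1c",
                         outcome = c("mace", "death"),
                         covariates = default_covariates(), k) {
  outcome <- match.arg(outcome)
  ds <- threshold_design(patients, exposure, outcome, covariates)
  if (k <= min(ds$x) || k >= max(ds$x))
    stop("breakpoint k = ", k, " outside the observed exposure range")
  d <- patients
  d$exposure_below <- pmin(ds$x, k)
  d$exposure_above <- pmax(ds$x - k, 0)
  fit <- weibull_aft(ds$fml(paste(c("exposure_below", "exposure_above",
                                    covariates), collapse = " + ")), d)
  attr(fit, "k") <- k
  attr(fit, "hr_below") <- hazard_ratio(fit, "exposure_below")
  attr(fit, "hr_above") <- hazard_ratio(fit, "exposure_above")
  fit
}

default_breakpoint_grid <- function(x, step = 0.01, lower = 0.05,
                                    upper = 0.95) {
  q <- quantile(x, c(lower, upper), names = FALSE)
  seq(q[1], q[2], by = step)
}

# Profile the two-piece log-likelihood over a breakpoint grid (C++ backend,
# warm-started). Returns the grid, profile log-likelihoods and slopes.
profile_breakpoints <- function(patients, exposure, outcome, covariates,
                                grid, start = NULL) {
  ds <- threshold_design(patients, exposure, outcome, covariates)
  rhs <- if (length(covariates))
    paste(covariates, collapse = " + ") else "1"
  mf <- model.frame(as.formula(paste0("~", rhs)), patients)
  X0 <- model.matrix(as.formula(paste0("~", rhs)), mf)
  time <- patients[[ds$oc$time]]
  event <- patients[[ds$oc$event]]
  if (is.null(start)) {
    one <- fit_onepiece(patients, exposure, outcome, covariates)
    co <- coef(one)
    slope <- co[[exposure]]
    beta0 <- c(co[c("(Intercept)", covariates)], slope, slope)
    s0 <- one$log_sigma
  } else {
    beta0 <- start$beta0
    s0 <- start$s0
  }
  pr <- aft_profile_cpp(X0, ds$x, log(time), event, grid,
                        as.numeric(beta0), s0)
  list(grid = grid, loglik = pr$loglik, beta_below = pr$beta_below,
       beta_above = pr$beta_above, sigma = pr$sigma,
       converged = pr$converged == 1)
}

#' Find the exposure inflection point by profile likelihood
#'
#' Scans a breakpoint grid (default: the 5th-95th exposure percentiles in
#' steps of 0.01%), fitting the two-piecewise adjusted Weibull AFT model at
#' each candidate; the inflection point is the grid argmax of the profile
#' log-likelihood (ties to the smallest candidate). Slope hazard ratios below
#' and above the selected breakpoint, and the curvature likelihood-ratio test
#' against the one-line model (df = 1), are reported. Segments with fewer
#' than 30 events are flagged as sparse.
#'
#' @inheritParams fit_onepiece
#' @param grid optional breakpoint grid (must lie inside the exposure range).
#' @param grid_step grid spacing when `grid` is not supplied.
#' @return object of class `threshold_fit`.
#' @export
find_inflection <- function(patients, exposure = "mean_hba1c",
                            outcome = c("mace", "death"),
                            covariates = default_covariates(),
                            grid = NULL, grid_step = 0.01) {
  outcome <- match.arg(outcome)
  ds <- threshold_design(patients, exposure, outcome, covariates)
  if (is.null(grid)) grid <- default_breakpoint_grid(ds$x, grid_step)
  grid <- sort(grid)
  if (grid[1] <= min(ds$x) || grid[length(grid)] >= max(ds$x))
    stop("breakpoint grid extends outside the observed exposure range")
  one <- fit_onepiece(patients, exposure, outcome, covariates)
  pr <- profile_breakpoints(patients, exposure, outcome, covariates, grid)
  ok <- pr$converged & is.finite(pr$loglik)
  if (!any(ok)) stop("no candidate breakpoint fit converged")
  ll <- ifelse(ok, pr$loglik, -Inf)
  k_hat <- grid[which.max(ll)]
  two <- fit_twopiece(patients, exposure, outcome, covariates, k = k_hat)
  curv <- lrt(two, one, df = 1)
  ev <- patients[[ds$oc$event]]
  n_below <- sum(ev == 1 & ds$x <= k_hat)
  n_above <- sum(ev == 1 & ds$x > k_hat)
  structure(list(
    inflection_k = k_hat, k_ci = NULL,
    hr_below = attr(two, "hr_below"), hr_above = attr(two, "hr_above"),
    hr_linear = attr(one, "hr"),
    p_curvature = curv$p_value,
    loglik_onepiece = one$loglik, loglik_twopiece = two$loglik,
    events_below = n_below, events_above = n_above,
    sparse_below = n_below < 30, sparse_above = n_above < 30,
    profile = data.frame(k = grid, loglik = pr$loglik,
                         converged = pr$converged),
    fit_onepiece = one, fit_twopiece = two,
    exposure = exposure, outcome = outcome, covariates = covariates,
    n_boot = 0L, seed = NULL),
    class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Two-piecewise threshold model (", x$outcome, " ~ ", x$exposure,
      ")\n", sep = "")
  ci <- if (!is.null(x$k_ci))
    sprintf(" (95%% CI %.2f-%.2f, %d bootstrap resamples)", x$k_ci[1],
            x$k_ci[2], x$n_boot) else ""
  cat(sprintf("  inflection point K = %.2f%%%s\n", x$inflection_k, ci))
  cat(sprintf("  HR below K: %.3f (%.3f-%.3f)%s\n", x$hr_below$hr,
              x$hr_below$ci_low, x$hr_below$ci_high,
              if (x$sparse_below) "  [sparse: <30 events]" else ""))
  cat(sprintf("  HR above K: %.3f (%.3f-%.3f)%s\n", x$hr_above$hr,
              x$hr_above$ci_low, x$hr_above$ci_high,
              if (x$sparse_above) "  [sparse: <30 events]" else ""))
  cat(sprintf("  one-line HR per 1%%: %.3f;  P curvature (LRT df=1): %.4g\n",
              x$hr_linear$hr, x$p_curvature))
  invisible(x)
}

#' Bootstrap confidence interval for the inflection point
#'
#' Resamples patients with replacement, re-runs the profile-likelihood
#' breakpoint search on each resample, and returns the percentile 2.5/97.5
#' interval of the bootstrap breakpoints. Deterministic given `seed`. The
#' search inside resamples uses a coarser grid (default step 0.05%) than the
#' main search; the discretization is far below the interval width.
#'
#' @param fit a [find_inflection()] result, or `NULL` to fit afresh.
#' @inheritParams fit_onepiece
#' @param n_boot number of bootstrap resamples (>= 200).
#' @param seed RNG seed for resampling.
#' @param grid_step breakpoint grid step inside resamples.
#' @param conf confidence level.
#' @return the `threshold_fit` with `k_ci`, `k_boot`, `n_boot`, `seed`
#'   filled in (errors if more than 20% of resample fits fail).
#' @export
bootstrap_inflection_ci <- function(fit, patients, n_boot = 500, seed = 1,
                                    grid_step = 0.05, conf = 0.95) {
  if (!inherits(fit, "threshold_fit")) stop("fit must be a threshold_fit")
  if (n_boot < 200) stop("n_boot must be at least 200")
  exposure <- fit$exposure
  outcome <- fit$outcome
  covariates <- fit$covariates
  x_all <- patients[[exposure]]
  n <- nrow(patients)
  start <- list(
    beta0 = c(coef(fit$fit_twopiece)[c("(Intercept)", covariates)],
              coef(fit$fit_twopiece)[c("exposure_below", "exposure_above")]),
    s0 = fit$fit_twopiece$log_sigma)
  k_boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(mix_seed(seed, 71L, b), sample.int(n, n, replace = TRUE))
    d <- patients[idx, , drop = FALSE]
    xb <- d[[exposure]]
    grid <- try(default_breakpoint_grid(xb, grid_step), silent = TRUE)
    if (inherits(grid, "try-error") || length(grid) < 1) next
    pr <- try(profile_breakpoints(d, exposure, outcome, covariates, grid,
                                  start = start), silent = TRUE)
    if (inherits(pr, "try-error")) next
    ok <- pr$converged & is.finite(pr$loglik)
    if (!any(ok)) next
    ll <- ifelse(ok, pr$loglik, -Inf)
    k_boot[b] <- grid[which.max(ll)]
  }
  n_fail <- sum(is.na(k_boot))
  if (n_fail > 0.2 * n_boot)
    stop("bootstrap breakpoint search failed in ", n_fail, " of ", n_boot,
         " resamples")
  alpha <- (1 - conf) / 2
  fit$k_ci <- unname(quantile(k_boot, c(alpha, 1 - alpha), na.rm = TRUE))
  fit$k_boot <- k_boot
  fit$n_boot <- as.integer(n_boot)
  fit$seed <- seed
  fit$n_boot_failed <- n_fail
  fit
}

#' Curvature likelihood-ratio test
#'
#' Compares the one-line exposure model with the two-piecewise model at the
#' selected breakpoint (df = 1, the breakpoint-selection convention of
#' two-piecewise practice; mildly anti-conservative because the breakpoint is
#' data-driven). A small p-value supports a curvilinear rather than linear
#' exposure-outcome relation.
#'
#' @param onepiece,twopiece fits from [fit_onepiece()] / [fit_twopiece()] on
#'   the same data and covariates.
#' @return list (class `glycvar_lrt`).
#' @export
curvature_lrt <- function(onepiece, twopiece) {
  if (onepiece$n != twopiece$n)
    stop("models must be fitted to the same data")
  lrt(twopiece, onepiece, df = 1)
}
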