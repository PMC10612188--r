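#' Parameters for a synthetic glycemic-variability cohort
#'
#' Bundles every knob of the synthetic cohort generator: visit-level HbA1c
#' trajectories with patient-specific volatility strata, Weibull-hazard
#' survival outcomes whose log hazard depends piecewise-linearly on each
#' patient's realized mean HbA1c, stratum-dependent treatment effects, and
#' administrative censoring.
#'
#' Defaults emulate a large glucose-lowering trial in high-risk type 2
#' diabetes: baseline HbA1c 8.3% (SD 1.1), a 50/50 randomization to an
#' intensive arm settling near 6.4% versus a standard arm near 7.5%, at least
#' four HbA1c measures in the first year followed by 4-monthly visits out to
#' five years, and crude event fractions of roughly 10% for the cardiovascular
#' composite (MACE) and 7% for all-cause death.
#'
#' @param n_patients number of patients.
#' @param arm_fraction probability of assignment to the intensive arm.
#' @param baseline_hba1c_mean,baseline_hba1c_sd baseline HbA1c distribution, %.
#' @param arm_targets named vector (`intensive`, `standard`): long-run HbA1c
#'   mean each arm approaches, %.
#' @param approach_halflife half-life (months) of the exponential approach
#'   from baseline toward the arm target.
#' @param ar1_rho autocorrelation of the AR(1) visit-to-visit shock process.
#' @param volatility_mixture list with `weight` and `shock_sd`: mixture of
#'   hidden volatility strata; `shock_sd` is the stationary SD (% HbA1c) of a
#'   patient's AR(1) shocks. Weights must sum to 1.
#' @param visit_schedule months of scheduled HbA1c measurements, strictly
#'   increasing with at least 4 visits in months 0--12.
#' @param weibull_shape Weibull shape of the event-time hazards (> 0).
#' @param baseline_log_hazard named vector (`mace`, `death`): log of the
#'   baseline Weibull rate parameter, per year.
#' @param effect_spec per-outcome piecewise exposure effects and per-stratum
#'   treatment effects; see [default_effect_spec()].
#' @param covariate_lhr named log hazard ratios for the adjustment covariates
#'   (applied to covariates centered at `covariate_center`).
#' @param covariate_center named centering constants for `covariate_lhr`.
#' @param censor_time administrative censoring horizon, years (> 0). Patients
#'   are additionally censored at a Uniform(3, censor_time) time.
#' @param single_visit_fraction fraction of patients whose record is truncated
#'   to the first visit only (planted metric-ineligible patients).
#' @param seed master RNG seed; all substreams derive from it.
#'
#' @return An object of class `cohort_params`.
#' @seealso [generate_cohort()], [generate_trajectory()], [simulate_outcome()]
#' @export
cohort_params <- function(n_patients = 10000,
                          arm_fraction = 0.5,
                          baseline_hba1c_mean = 8.3,
                          baseline_hba1c_sd = 1.1,
                          arm_targets = c(intensive = 6.4, standard = 7.5),
                          approach_halflife = 6,
                          ar1_rho = 0.3,
                          volatility_mixture = list(
                            weight = c(0.45, 0.39, 0.16),
                            shock_sd = c(0.3, 0.6, 1.0)),
                          visit_schedule = c(0, 2, 4, 6, 8, 10, 12,
                                             seq(16, 60, by = 4)),
                          weibull_shape = 1.2,
                          baseline_log_hazard = c(mace = -3.55, death = -3.9),
                          effect_spec = default_effect_spec(),
                          covariate_lhr = c(age = 0.03, female = -0.2,
                                            bmi = 0.01, sbp = 0.005,
                                            egfr = -0.005, smoking = 0.35),
                          covariate_center = c(age = 62.7, female = 0,
                                               bmi = 32.3, sbp = 136.4,
                                               egfr = 91, smoking = 0),
                          censor_time = 5,
                          single_visit_fraction = 0,
                          seed = 1) {
  p <- list(n_patients = as.integer(n_patients), arm_fraction = arm_fraction,
            baseline_hba1c_mean = baseline_hba1c_mean,
            baseline_hba1c_sd = baseline_hba1c_sd,
            arm_targets = arm_targets, approach_halflife = approach_halflife,
            ar1_rho = ar1_rho, volatility_mixture = volatility_mixture,
            visit_schedule = visit_schedule, weibull_shape = weibull_shape,
            baseline_log_hazard = baseline_log_hazard,
            effect_spec = effect_spec, covariate_lhr = covariate_lhr,
            covariate_center = covariate_center, censor_time = censor_time,
            single_visit_fraction = single_visit_fraction,
            seed = as.integer(seed))
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

#' Default piecewise exposure and treatment effect specification
#'
#' For each outcome and hidden volatility stratum (low, medium, high) the log
#' hazard depends on the patient's realized mean HbA1c through a continuous
#' hinge: slope `slope_below` up to the breakpoint `k` and `slope_above`
#' beyond it (both log HR per 1% HbA1c; `k = NA` means a single straight
#' line). `treat_lhr` is the stratum-specific treatment log hazard ratio.
#' The spec is centered so the exposure term vanishes at `center`.
#'
#' The defaults encode, as generative truth, the qualitative pattern this
#' package is designed to recover: a protective intensive-treatment effect in
#' the low-variability stratum and a harmful one in the high stratum, a
#' monotone MACE dose-response in mean HbA1c, and a U-shaped mortality
#' relation with a breakpoint near 7.4% in the medium stratum.
#'
#' @param center exposure value (% HbA1c) at which the exposure term is zero.
#' @return a list with components `mace`, `death` and `center`.
#' @export
default_effect_spec <- function(center = 7.5) {
  list(
    mace = list(
      k = c(NA, 7.49, NA),
      slope_below = log(c(1.33, 0.88, 1.06)),
      slope_above = log(c(1.33, 1.38, 1.06)),
      treat_lhr = log(c(0.78, 1.3, 2.0))),
    death = list(
      k = c(NA, 7.44, 7.86),
      slope_below = log(c(1.23, 0.49, 0.63)),
      slope_above = log(c(1.23, 1.57, 1.01)),
      treat_lhr = log(c(1.07, 1.3, 2.2))),
    center = center)
}

validate_cohort_params <- function(p) {
  w <- p$volatility_mixture$weight
  sds <- p$volatility_mixture$shock_sd
  if (is.null(w) || is.null(sds) || length(w) != length(sds))
    stop("volatility_mixture needs equal-length 'weight' and 'shock_sd'")
  if (abs(sum(w) - 1) > 1e-8) stop("volatility mixture weights must sum to 1")
  if (any(sds < 0)) stop("volatility shock SDs must be >= 0")
  vs <- p$visit_schedule
  if (any(diff(vs) <= 0)) stop("visit_schedule must be strictly increasing")
  if (sum(vs >= 0 & vs <= 12) < 4)
    stop("visit_schedule needs at least 4 visits in months 0-12")
  if (p$censor_time <= 0) stop("censor_time must be > 0")
  if (p$weibull_shape <= 0) stop("weibull_shape must be > 0")
  if (p$arm_fraction < 0 || p$arm_fraction > 1)
    stop("arm_fraction must be in [0, 1]")
  if (!all(c("intensive", "standard") %in% names(p$arm_targets)))
    stop("arm_targets must name 'intensive' and 'standard'")
  if (p$single_visit_fraction < 0 || p$single_visit_fraction > 1)
    stop("single_visit_fraction must be in [0, 1]")
  invisible(p)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat("  n_patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  arm targets (%):", paste(names(x$arm_targets), x$arm_targets,
                                  sep = "=", collapse = ", "), "\n")
  cat("  volatility strata (weight @ shock SD):",
      paste(sprintf("%.2f@%.2f", x$volatility_mixture$weight,
                    x$volatility_mixture$shock_sd), collapse = ", "), "\n")
  cat("  visits:", length(x$visit_schedule), "over",
      max(x$visit_schedule), "months;  censor at", x$censor_time, "y\n")
  invisible(x)
}

# continuous hinge exposure term, centered at `center`
piecewise_lp <- function(x, k, slope_below, slope_above, center) {
  f <- function(v) {
    if (is.na(k)) slope_below * v
    else slope_below * pmin(v, k) + slope_above * pmax(v - k, 0)
  }
  f(x) - f(center)
}

#' Generate one patient's HbA1c trajectory
#'
#' The trajectory is an exponential approach from a random baseline toward the
#' arm target (half-life `approach_halflife` months) plus stationary AR(1)
#' shocks whose SD is set by the patient's hidden volatility stratum. Values
#' are clipped to the physiologic range (3, 20)%.
#'
#' @param params a [cohort_params()] object.
#' @param arm `"intensive"` or `"standard"`.
#' @param stratum index into `params$volatility_mixture`.
#' @param seed RNG substream seed; the same seed reproduces the trajectory
#'   bit for bit.
#' @param patient_id identifier stored on the result.
#' @return object of class `hba1c_trajectory` with `times` (months) and
#'   `values` (% HbA1c).
#' @export
generate_trajectory <- function(params, arm, stratum, seed,
                                patient_id = NA_character_) {
  nm <- length(params$volatility_mixture$shock_sd)
  if (!(is.numeric(stratum) && length(stratum) == 1 && stratum >= 1 &&
        stratum <= nm))
    stop("unknown volatility stratum: ", stratum)
  if (!arm %in% names(params$arm_targets)) stop("unknown arm: ", arm)
  tv <- params$visit_schedule
  vals <- with_seed(seed, {
    b <- rnorm(1, params$baseline_hba1c_mean, params$baseline_hba1c_sd)
    innov <- rnorm(length(tv))
    traj_values(params, arm, stratum, b, innov)
  })
  new_trajectory(patient_id, tv, vals)
}

# deterministic trajectory kernel given baseline and standard-normal innovations
traj_values <- function(params, arm, stratum, baseline, innov) {
  tv <- params$visit_schedule
  target <- unname(params$arm_targets[[arm]])
  mu <- target + (baseline - target) * 2^(-tv / params$approach_halflife)
  sd_s <- params$volatility_mixture$shock_sd[stratum]
  rho <- params$ar1_rho
  n <- length(tv)
  e <- numeric(n)
  if (sd_s > 0) {
    e[1] <- sd_s * innov[1]
    if (n > 1) {
      si <- sd_s * sqrt(1 - rho^2)
      for (i in 2:n) e[i] <- rho * e[i - 1] + si * innov[i]
    }
  }
  pmin(pmax(mu + e, 3 + 1e-6), 20 - 1e-6)
}

new_trajectory <- function(patient_id, times, values) {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (length(values) < 1) stop("trajectory needs at least one measurement")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(values <= 3 | values >= 20))
    stop("HbA1c values must lie in (3, 20)%")
  structure(list(patient_id = patient_id, times = times, values = values),
            class = "hba1c_trajectory")
}

#' @export
print.hba1c_trajectory <- function(x, ...) {
  cat("HbA1c trajectory", if (!is.na(x$patient_id)) paste0("(", x$patient_id, ")"),
      "-", length(x$values), "visits over", max(x$times), "months\n")
  cat("  values:", paste(sprintf("%.1f", head(x$values, 8)), collapse = " "),
      if (length(x$values) > 8) "...", "\n")
  invisible(x)
}

# Inverse-CDF draw from the Weibull proportional-hazards model
# H(t) = (lambda t)^shape * exp(lp); E ~ Exp(1).
weibull_ph_time <- function(E, lp, shape, lambda) {
  (E * exp(-lp))^(1 / shape) / lambda
}

#' Simulate survival outcomes under a Weibull proportional-hazards model
#'
#' Event times follow hazard `h0(t) exp(lp)` with Weibull baseline
#' `H0(t) = (lambda t)^shape`. Each record is censored at
#' `min(censor_time, Uniform(3, censor_time))` (administrative censoring with
#' staggered withdrawal); set `censor = FALSE` for uncensored event times.
#'
#' @param linear_predictor vector of log-hazard offsets.
#' @param params a [cohort_params()] object (supplies shape, baseline log
#'   hazard, censor time).
#' @param seed RNG substream seed.
#' @param outcome which baseline hazard to use (`"mace"` or `"death"`).
#' @param censor apply administrative censoring (default TRUE).
#' @return data.frame with columns `time` (years) and `event` (0/1).
#' @export
simulate_outcome <- function(linear_predictor, params, seed,
                             outcome = "mace", censor = TRUE) {
  if (params$weibull_shape <= 0) stop("weibull_shape must be > 0")
  lambda <- exp(unname(params$baseline_log_hazard[[outcome]]))
  n <- length(linear_predictor)
  with_seed(seed, {
    E <- -log(runif(n))
    Tt <- weibull_ph_time(E, linear_predictor, params$weibull_shape, lambda)
    if (censor) {
      C <- pmin(params$censor_time,
                runif(n, min(3, params$censor_time), params$censor_time))
      data.frame(time = pmin(Tt, C), event = as.integer(Tt <= C))
    } else {
      data.frame(time = Tt, event = 1L)
    }
  })
}

#' Generate a complete synthetic cohort
#'
#' Draws, for each patient: a hidden volatility stratum and treatment arm,
#' adjustment covariates, a visit-level HbA1c trajectory, and Weibull
#' survival outcomes (MACE and all-cause death) whose log hazard combines the
#' piecewise effect of the patient's realized mean HbA1c, the
#' stratum-specific treatment effect, and covariate effects. Every patient
#' owns independent RNG substreams, so enlarging the cohort leaves existing
#' patients' data unchanged.
#'
#' @param params a [cohort_params()] object.
#' @return object of class `hba1c_cohort`: a list with `visits` (long
#'   data.frame: patient_id, month, hba1c), `patients` (one row per patient
#'   with arm, covariates, outcome times/indicators), `truth` (hidden stratum,
#'   realized mean HbA1c and linear predictors, for recovery testing), and
#'   `params`.
#' @export
generate_cohort <- function(params) {
  validate_cohort_params(params)
  n <- params$n_patients
  if (n == 0) {
    return(structure(list(
      visits = data.frame(patient_id = character(), month = numeric(),
                          hba1c = numeric()),
      patients = empty_patients_df(),
      truth = data.frame(patient_id = character(), stratum = integer(),
                         mean_hba1c = numeric(), lp_mace = numeric(),
                         lp_death = numeric()),
      params = params), class = "hba1c_cohort"))
  }
  tv <- params$visit_schedule
  nv <- length(tv)
  wts <- cumsum(params$volatility_mixture$weight)
  ids <- sprintf("P%06d", seq_len(n))

  arm <- character(n); stratum <- integer(n)
  age <- numeric(n); female <- integer(n); bmi <- numeric(n)
  sbp <- numeric(n); egfr <- numeric(n); smoking <- integer(n)
  nvis <- integer(n)
  values <- matrix(NA_real_, n, nv)
  E_mace <- numeric(n); E_death <- numeric(n); C <- numeric(n)

  for (i in seq_len(n)) {
    # patient-level stream: design + covariates
    with_seed(mix_seed(params$seed, 1L, i), {
      u <- runif(3)
      arm[i] <- if (u[1] < params$arm_fraction) "intensive" else "standard"
      stratum[i] <- findInterval(u[2], wts, left.open = TRUE) + 1L
      nvis[i] <- if (u[3] < params$single_visit_fraction) 1L else nv
      age[i] <- min(max(rnorm(1, 62.7, 6.6), 40), 85)
      female[i] <- as.integer(runif(1) < 0.384)
      bmi[i] <- min(max(rnorm(1, 32.3, 5.4), 17), 55)
      sbp[i] <- min(max(rnorm(1, 136.4, 17), 85), 210)
      egfr[i] <- min(max(rnorm(1, 91, 27), 15), 180)
      smoking[i] <- as.integer(runif(1) < 0.14)
    })
    # trajectory stream
    with_seed(mix_seed(params$seed, 2L, i), {
      b <- rnorm(1, params$baseline_hba1c_mean, params$baseline_hba1c_sd)
      innov <- rnorm(nv)
      values[i, ] <- traj_values(params, arm[i], stratum[i], b, innov)
    })
    # outcome stream
    with_seed(mix_seed(params$seed, 3L, i), {
      u <- runif(2)
      E_mace[i] <- -log(u[1]); E_death[i] <- -log(u[2])
    })
    # censoring stream
    with_seed(mix_seed(params$seed, 4L, i), {
      C[i] <- min(params$censor_time,
                   runif(1, min(3, params$censor_time), params$censor_time))
    })
  }

  mean_hba1c <- rowMeans(values)
  cc <- params$covariate_center
  cov_lp <- params$covariate_lhr[["age"]] * (age - cc[["age"]]) +
    params$covariate_lhr[["female"]] * (female - cc[["female"]]) +
    params$covariate_lhr[["bmi"]] * (bmi - cc[["bmi"]]) +
    params$covariate_lhr[["sbp"]] * (sbp - cc[["sbp"]]) +
    params$covariate_lhr[["egfr"]] * (egfr - cc[["egfr"]]) +
    params$covariate_lhr[["smoking"]] * (smoking - cc[["smoking"]])

  lp_for <- function(spec) {
    expo <- numeric(n)
    for (s in unique(stratum)) {
      sel <- stratum == s
      expo[sel] <- piecewise_lp(mean_hba1c[sel], spec$k[s],
                                spec$slope_below[s], spec$slope_above[s],
                                params$effect_spec$center)
    }
    expo + spec$treat_lhr[stratum] * (arm == "intensive") + cov_lp
  }
  lp_mace <- lp_for(params$effect_spec$mace)
  lp_death <- lp_for(params$effect_spec$death)

  shape <- params$weibull_shape
  t_mace <- weibull_ph_time(E_mace, lp_mace, shape,
                            exp(params$baseline_log_hazard[["mace"]]))
  t_death <- weibull_ph_time(E_death, lp_death, shape,
                             exp(params$baseline_log_hazard[["death"]]))
  # death truncates MACE follow-up; both share the administrative censor
  c_mace <- pmin(C, t_death)

  patients <- data.frame(
    patient_id = ids,
    arm = factor(arm, levels = c("standard", "intensive")),
    age = age, female = female, bmi = bmi, sbp = sbp, egfr = egfr,
    smoking = smoking,
    time_mace = pmin(t_mace, c_mace),
    event_mace = as.integer(t_mace <= c_mace),
    time_death = pmin(t_death, C),
    event_death = as.integer(t_death <= C),
    stringsAsFactors = FALSE)

  keep <- rep(seq_len(n), nvis)
  vidx <- sequence(nvis)
  visits <- data.frame(
    patient_id = ids[keep],
    month = tv[vidx],
    hba1c = values[cbind(keep, vidx)],
    stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = ids, stratum = stratum,
                      mean_hba1c = mean_hba1c, lp_mace = lp_mace,
                      lp_death = lp_death, stringsAsFactors = FALSE)

  structure(list(visits = visits, patients = patients, truth = truth,
                 params = params),
            class = "hba1c_cohort")
}

empty_patients_df <- function() {
  data.frame(patient_id = character(), arm = factor(levels = c("standard",
             "intensive")), age = numeric(), female = integer(),
             bmi = numeric(), sbp = numeric(), egfr = numeric(),
             smoking = integer(), time_mace = numeric(),
             event_mace = integer(), time_death = numeric(),
             event_death = integer(), stringsAsFactors = FALSE)
}

#' @export
print.hba1c_cohort <- function(x, ...) {
  n <- nrow(x$patients)
  cat("Synthetic HbA1c cohort:", n, "patients,",
      nrow(x$visits), "visits\n")
  if (n > 0) {
    cat("  intensive arm:", sum(x$patients$arm == "intensive"),
        sprintf("(%.1f%%)", 100 * mean(x$patients$arm == "intensive")), "\n")
    cat(sprintf("  events: MACE %d (%.1f%%), death %d (%.1f%%)\n",
                sum(x$patients$event_mace),
                100 * mean(x$patients$event_mace),
                sum(x$patients$event_death),
                100 * mean(x$patients$event_death)))
  }
  invisible(x)
}

#' Write a cohort to delimited files
#'
#' Writes `visits.csv`, `patients.csv`, `truth.csv` and a `params.json`
#' sidecar with the generative parameters.
#'
#' @param cohort an `hba1c_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  write.csv(cohort$patients, file.path(dir, "patients.csv"),
            row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  p <- unclass(cohort$params)
  jsonlite::write_json(p, file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read visit / patient tables written by [write_cohort()]
#' @param path file path to a delimited table.
#' @return data.frame.
#' @export
read_visits <- function(path) {
  v <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "month", "hba1c")
  if (!all(need %in% names(v)))
    stop("visits file must have columns: ", paste(need, collapse = ", "))
  v
}

#' @rdname read_visits
#' @export
read_patients <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "time_mace", "event_mace", "time_death",
            "event_death")
  if (!all(need %in% names(p)))
    stop("patients file must have columns: ", paste(need, collapse = ", "))
  p$arm <- factor(p$arm, levels = c("standard", "intensive"))
  p
}
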