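#' HbA1c variability score (HVS)
#'
#' Percentage of successive visit-to-visit HbA1c changes whose absolute value
#' strictly exceeds 0.5 percentage points. Visits are ordered by time before
#' differencing; duplicate timestamps are an error. With
#' `denominator = "intervals"` (default) the count is divided by the number of
#' successive changes (n - 1); `"measures"` divides by the number of
#' measurements n.
#'
#' @param x an `hba1c_trajectory` or a numeric vector of HbA1c values.
#' @param times measurement times; defaults to the trajectory's times or the
#'   vector order.
#' @param denominator `"intervals"` (n - 1) or `"measures"` (n).
#' @param threshold change threshold, % HbA1c (strict inequality).
#' @return HVS in [0, 100].
#' @export
hvs <- function(x, times = NULL, denominator = c("intervals", "measures"),
                threshold = 0.5) {
  denominator <- match.arg(denominator)
  v <- metric_values(x, times, min_n = 2,
                     what = "HVS requires at least 2 HbA1c measures")
  n <- length(v)
  nc <- sum(abs(diff(v)) > threshold)
  100 * nc / if (denominator == "intervals") n - 1 else n
}

#' Standard deviation of HbA1c
#'
#' Sample standard deviation (n - 1 denominator by default) of all HbA1c
#' measurements within a patient.
#'
#' @inheritParams hvs
#' @param denominator `"n-1"` (sample, default) or `"n"` (population).
#' @return SD in % HbA1c units.
#' @export
sd_hba1c <- function(x, times = NULL, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  v <- metric_values(x, times, min_n = 2,
                     what = "SD requires at least 2 HbA1c measures")
  s2 <- sum((v - mean(v))^2)
  n <- length(v)
  sqrt(s2 / if (denominator == "n-1") n - 1 else n)
}

#' Mean HbA1c over all visits
#'
#' @inheritParams hvs
#' @return arithmetic mean, % HbA1c.
#' @export
mean_hba1c <- function(x, times = NULL) {
  v <- metric_values(x, times, min_n = 1,
                     what = "mean requires at least 1 HbA1c measure")
  mean(v)
}

# shared extraction: sort by time, check duplicates and eligibility
metric_values <- function(x, times, min_n, what) {
  if (inherits(x, "hba1c_trajectory")) {
    v <- x$values
    tt <- x$times
  } else {
    v <- as.numeric(x)
    tt <- if (is.null(times)) seq_along(v) else times
  }
  if (length(v) != length(tt)) stop("values and times differ in length")
  if (anyDuplicated(tt)) stop("duplicate measurement times")
  if (length(v) < min_n) {
    stop(structure(class = c("glycvar_ineligible", "error", "condition"),
                   list(message = what, call = sys.call(-1))))
  }
  v[order(tt)]
}

#' Per-patient variability metrics from a long visit table
#'
#' Computes, for every patient in a long-format visit table, the number of
#' measures, HVS, SD and mean HbA1c. Patients with fewer than 2 measures get
#' `NA` for HVS and SD (their HVS is incomputable); mean HbA1c is reported
#' whenever at least one measure exists.
#'
#' @param visits data.frame with columns `patient_id`, `month`, `hba1c`.
#' @param hvs_denominator,sd_denominator passed to [hvs()] / [sd_hba1c()].
#' @return data.frame: `patient_id`, `n_measures`, `hvs`, `sd`, `mean_hba1c`.
#' @export
compute_metrics <- function(visits, hvs_denominator = c("intervals",
                            "measures"), sd_denominator = c("n-1", "n")) {
  hvs_denominator <- match.arg(hvs_denominator)
  sd_denominator <- match.arg(sd_denominator)
  need <- c("patient_id", "month", "hba1c")
  if (!all(need %in% names(visits)))
    stop("visits must have columns: ", paste(need, collapse = ", "))
  o <- order(visits$patient_id, visits$month)
  id <- as.character(visits$patient_id)[o]
  tt <- visits$month[o]
  x <- visits$hba1c[o]
  r <- rle(id)
  n_i <- r$lengths
  uid <- r$values
  # duplicate timestamps within patient
  m <- length(id)
  if (m > 1 && any(id[-1] == id[-m] & tt[-1] == tt[-m]))
    stop("duplicate measurement times within patient")
  g <- rep(seq_along(n_i), n_i)
  sums <- rowsum(x, g)[, 1]
  sq <- rowsum(x^2, g)[, 1]
  means <- sums / n_i
  ss <- pmax(sq - n_i * means^2, 0)
  sdv <- ifelse(n_i >= 2,
                sqrt(ss / if (sd_denominator == "n-1") n_i - 1 else n_i), NA)
  d <- diff(x)
  within <- g[-1] == g[-length(g)]
  big <- as.numeric(abs(d) > 0.5 & within)
  nbig <- rowsum(c(0, big), g)[, 1]
  hvsv <- ifelse(n_i >= 2,
                 100 * nbig /
                   if (hvs_denominator == "intervals") n_i - 1 else n_i, NA)
  data.frame(patient_id = uid, n_measures = as.integer(n_i), hvs = hvsv,
             sd = sdv, mean_hba1c = means, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit the variation-independent-of-the-mean (VIM) exponent
#'
#' VIM rescales the per-patient SD as
#' `VIM_i = population_mean^x * sd_i / mean_i^x`, with the exponent `x`
#' estimated by ordinary least squares of `log(sd_i)` on `log(mean_i)` across
#' patients. By construction, VIM computed with the fitted `x` is (nearly)
#' uncorrelated with the patient mean, unlike the raw SD. Patients with
#' `sd = 0` or non-positive mean are excluded from the fit (the log is
#' undefined); the number of exclusions is recorded.
#'
#' @param metrics data.frame from [compute_metrics()] (needs columns `sd`,
#'   `mean_hba1c`).
#' @return object of class `vim_model`: `exponent_x`, `population_mean`,
#'   `fit_r2`, `n_patients_fit`, `n_excluded`.
#' @export
fit_vim_model <- function(metrics) {
  ok <- !is.na(metrics$sd) & !is.na(metrics$mean_hba1c) &
    metrics$sd > 0 & metrics$mean_hba1c > 0
  n_ok <- sum(ok)
  if (n_ok < 3)
    stop("VIM exponent fit needs at least 3 patients with sd > 0 and mean > 0")
  lmn <- log(metrics$mean_hba1c[ok])
  lsd <- log(metrics$sd[ok])
  if (var(lmn) < 1e-12)
    stop("VIM exponent unidentifiable: all patient means are equal")
  fit <- lm(lsd ~ lmn)
  structure(list(exponent_x = unname(coef(fit)[2]),
                 population_mean = mean(metrics$mean_hba1c[ok]),
                 fit_r2 = summary(fit)$r.squared,
                 n_patients_fit = n_ok,
                 n_excluded = sum(!ok)),
            class = "vim_model")
}

#' @export
print.vim_model <- function(x, ...) {
  cat(sprintf(
    "VIM model: x = %.4f (r2 = %.3f), population mean = %.3f%%, fit on %d patients (%d excluded)\n",
    x$exponent_x, x$fit_r2, x$population_mean, x$n_patients_fit,
    x$n_excluded))
  invisible(x)
}

#' Per-patient VIM values
#'
#' @param metrics data.frame with `sd` and `mean_hba1c` columns.
#' @param model a fitted [fit_vim_model()] object.
#' @return numeric vector of VIM values (same scale as SD); `NA` where SD is
#'   missing.
#' @export
vim <- function(metrics, model) {
  if (!inherits(model, "vim_model")) stop("'model' must be a fitted vim_model")
  if (any(metrics$mean_hba1c <= 0, na.rm = TRUE))
    stop("VIM requires positive patient means")
  x <- model$exponent_x
  model$population_mean^x * metrics$sd / metrics$mean_hba1c^x
}
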