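#' Configuration for a full variability analysis run
#'
#' One declarative object drives the whole pipeline: data source (existing
#' visit/patient tables or a synthetic-cohort simulation block), metric
#' conventions, clustering settings, outcomes, adjustment covariates,
#' sensitivity flags and bootstrap settings.
#'
#' @param simulate a [cohort_params()] object, or `NULL` when `visits` /
#'   `patients` are given.
#' @param visits,patients data.frames or file paths (long visit table and
#'   patient-level table).
#' @param hvs_denominator,sd_denominator metric conventions (see [hvs()],
#'   [sd_hba1c()]).
#' @param k number of variability groups (fixed at 3 for the grouped
#'   analyses).
#' @param k_range candidate k scanned by [select_k()] (subset of 2..9); set
#'   `select_k = FALSE` to skip the scan.
#' @param select_k logical; run the internal-validation scan over `k_range`.
#' @param scale `"zscore"` (standardize features) or `"none"`.
#' @param seed master seed for clustering restarts and bootstrap.
#' @param n_init clustering restarts.
#' @param outcomes outcomes to analyse (`"mace"`, `"death"`).
#' @param covariates adjustment covariates present in the patients table.
#' @param min_followup_years sensitivity exclusion: drop patients followed
#'   for less than this many years (0 disables).
#' @param use_vim sensitivity: additionally cluster on (HVS, VIM) and report
#'   agreement with the main (HVS, SD) grouping.
#' @param n_boot bootstrap resamples for inflection-point CIs (0 disables
#'   the bootstrap).
#' @param grid_step,boot_grid_step breakpoint grid steps (main search /
#'   inside bootstrap resamples).
#' @param smooth_df spline basis dimension for the smooth curves.
#' @return object of class `run_config`.
#' @export
run_config <- function(simulate = cohort_params(), visits = NULL,
                       patients = NULL,
                       hvs_denominator = c("intervals", "measures"),
                       sd_denominator = c("n-1", "n"), k = 3,
                       k_range = 2:9, select_k = TRUE,
                       scale = c("zscore", "none"), seed = 7, n_init = 20,
                       outcomes = c("mace", "death"),
                       covariates = default_covariates(),
                       min_followup_years = 0, use_vim = FALSE,
                       n_boot = 200, grid_step = 0.01,
                       boot_grid_step = 0.05, smooth_df = 4) {
  hvs_denominator <- match.arg(hvs_denominator)
  sd_denominator <- match.arg(sd_denominator)
  scale <- match.arg(scale)
  if (is.null(simulate) && (is.null(visits) || is.null(patients)))
    stop("either a simulate block or visits + patients must be provided")
  if (!is.null(simulate) && !inherits(simulate, "cohort_params"))
    stop("simulate must be a cohort_params object")
  if (any(k_range < 2) || any(k_range > 9))
    stop("k_range must be a subset of 2..9")
  if (min_followup_years < 0) stop("min_followup_years must be >= 0")
  for (nm in c("visits", "patients")) {
    v <- get(nm)
    if (is.character(v) && !file.exists(v)) stop(nm, " file not found: ", v)
  }
  structure(list(simulate = simulate, visits = visits, patients = patients,
                 hvs_denominator = hvs_denominator,
                 sd_denominator = sd_denominator, k = k, k_range = k_range,
                 select_k = select_k, scale = scale, seed = seed,
                 n_init = n_init, outcomes = outcomes,
                 covariates = covariates,
                 min_followup_years = min_followup_years, use_vim = use_vim,
                 n_boot = n_boot, grid_step = grid_step,
                 boot_grid_step = boot_grid_step, smooth_df = smooth_df),
            class = "run_config")
}

#' Apply eligibility rules to a cohort
#'
#' Drops patients whose HVS cannot be computed (fewer than 2 HbA1c measures)
#' and, when `min_followup_years > 0`, patients with shorter follow-up
#' (death/censoring time). Exclusions are logged per patient with a reason.
#'
#' @param visits long visit table.
#' @param patients patient-level table.
#' @param min_measures minimum HbA1c measures (default 2).
#' @param min_followup_years sensitivity follow-up floor (0 disables).
#' @return list: `visits`, `patients` (filtered), `exclusions` (data.frame
#'   patient_id, reason). Orphan visits (no patient record) are an error.
#' @export
apply_eligibility <- function(visits, patients, min_measures = 2,
                              min_followup_years = 0) {
  orphans <- setdiff(unique(visits$patient_id), patients$patient_id)
  if (length(orphans))
    stop("visits reference unknown patient id(s): ",
         paste(head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) " ...")
  counts <- table(factor(visits$patient_id, levels = patients$patient_id))
  few <- patients$patient_id[counts < min_measures]
  exclusions <- data.frame(patient_id = as.character(few),
                           reason = rep("hvs_incomputable", length(few)),
                           stringsAsFactors = FALSE)
  if (min_followup_years > 0) {
    fu <- patients$time_death
    short <- patients$patient_id[fu < min_followup_years &
                                   !patients$patient_id %in% few]
    exclusions <- rbind(exclusions,
                        data.frame(patient_id = as.character(short),
                                   reason = rep("short_followup",
                                                length(short)),
                                   stringsAsFactors = FALSE))
  }
  keep <- !patients$patient_id %in% exclusions$patient_id
  list(visits = visits[visits$patient_id %in% patients$patient_id[keep], ,
                       drop = FALSE],
       patients = patients[keep, , drop = FALSE],
       exclusions = exclusions)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full variability analysis pipeline
#'
#' Orchestrates the end-to-end analysis from one [run_config()]:
#' eligibility filtering, per-patient variability metrics (with the VIM
#' model), K-means / K-medians / quantile grouping with internal-validation
#' scans, a descriptive group summary, stratified treatment hazard ratios
#' with interaction and trend tests, two-piecewise threshold reports per
#' group and outcome, smooth HR curves, and a machine-readable manifest. All
#' randomness flows from `config$seed` (plus the simulation's own seed), so
#' a fixed config reproduces the report bundle exactly.
#'
#' @param config a [run_config()] object.
#' @return object of class `gv_report`: list with `metrics`, `assignments`,
#'   `validation`, `group_summary`, `treatment_effects`, `thresholds`,
#'   `curves`, `exclusions`, `manifest`.
#' @seealso [write_report()]
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  cov <- config$covariates

  src <- run_stage("data", {
    if (!is.null(config$visits) && !is.null(config$patients)) {
      v <- if (is.character(config$visits)) read_visits(config$visits)
           else config$visits
      p <- if (is.character(config$patients)) read_patients(config$patients)
           else config$patients
      if (!is.factor(p$arm))
        p$arm <- factor(p$arm, levels = c("standard", "intensive"))
      list(visits = v, patients = p)
    } else {
      co <- generate_cohort(config$simulate)
      list(visits = co$visits, patients = co$patients)
    }
  })
  n_input <- nrow(src$patients)

  elig <- run_stage("eligibility",
    apply_eligibility(src$visits, src$patients, min_measures = 2,
                      min_followup_years = config$min_followup_years))

  metrics <- run_stage("metrics", {
    m <- compute_metrics(elig$visits,
                         hvs_denominator = config$hvs_denominator,
                         sd_denominator = config$sd_denominator)
    m <- m[match(elig$patients$patient_id, m$patient_id), , drop = FALSE]
    vm <- fit_vim_model(m)
    m$vim <- vim(m, vm)
    attr(m, "vim_model") <- vm
    m
  })

  clus <- run_stage("clustering", {
    feats <- standardize_features(metrics[, c("hvs", "sd")], config$scale)
    validation <- NULL
    chosen <- list()
    models <- list()
    for (meth in c("kmeans", "kmedians")) {
      if (config$select_k) {
        sel <- select_k(feats, config$k_range, method = meth,
                        seed = config$seed, n_init = config$n_init)
        validation <- rbind(validation,
                            cbind(method = meth, sel$scores,
                                  chosen = sel$scores$k == sel$k))
        chosen[[meth]] <- sel$k
        fit <- if (as.character(config$k) %in% names(sel$models))
          sel$models[[as.character(config$k)]]
        else NULL
      } else fit <- NULL
      if (is.null(fit)) {
        fitter <- if (meth == "kmeans") kmeans_fit else kmedians_fit
        fit <- fitter(feats, config$k,
                      seed = mix_seed(config$seed, 11L, config$k),
                      n_init = config$n_init)
      }
      models[[meth]] <- order_clusters(fit, metrics$hvs)
    }
    qgrp <- factor(c("low", "medium", "high")[quantile_clusters(metrics$hvs)],
                   levels = c("low", "medium", "high"))
    assignments <- data.frame(
      patient_id = metrics$patient_id,
      kmeans = cluster_groups(models$kmeans),
      kmedians = cluster_groups(models$kmedians),
      quantile = qgrp, stringsAsFactors = FALSE)
    vim_agreement <- NULL
    if (config$use_vim) {
      fv <- standardize_features(metrics[, c("hvs", "vim")], config$scale)
      mv <- order_clusters(
        kmeans_fit(fv, config$k, seed = mix_seed(config$seed, 13L, config$k),
                   n_init = config$n_init), metrics$hvs)
      assignments$kmeans_vim <- cluster_groups(mv)
      vim_agreement <- mean(assignments$kmeans == assignments$kmeans_vim)
    }
    list(models = models, assignments = assignments,
         validation = validation, chosen_k = chosen,
         vim_agreement = vim_agreement)
  })

  groups <- clus$assignments$kmeans
  patients <- elig$patients
  analysis <- cbind(patients,
                    metrics[, c("n_measures", "hvs", "sd", "mean_hba1c",
                                "vim")])

  group_summary <- run_stage("group_summary", {
    base <- elig$visits[elig$visits$month == min(elig$visits$month), ]
    base_hba1c <- base$hba1c[match(patients$patient_id, base$patient_id)]
    do.call(rbind, lapply(levels(groups), function(g) {
      sel <- groups == g
      data.frame(group = g, n = sum(sel),
                 pct = 100 * mean(sel),
                 hvs_mean = mean(metrics$hvs[sel]),
                 hvs_sd = sd(metrics$hvs[sel]),
                 sd_mean = mean(metrics$sd[sel]),
                 sd_sd = sd(metrics$sd[sel]),
                 baseline_hba1c_mean = mean(base_hba1c[sel], na.rm = TRUE),
                 mean_hba1c = mean(metrics$mean_hba1c[sel]),
                 intensive_pct = 100 * mean(patients$arm[sel] == "intensive"),
                 mace_pct = 100 * mean(patients$event_mace[sel]),
                 death_pct = 100 * mean(patients$event_death[sel]),
                 stringsAsFactors = FALSE)
    }))
  })

  treatment_effects <- run_stage("stratified_hr", {
    out <- list()
    for (meth in c("kmeans", "kmedians")) {
      for (oc in config$outcomes) {
        s <- stratified_treatment_hr(patients, clus$assignments[[meth]],
                                     outcome = oc, covariates = cov)
        out[[paste(meth, oc, sep = ".")]] <-
          cbind(method = meth, outcome = oc, s$by_group,
                p_interaction = s$p_interaction, p_trend = s$p_trend)
      }
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })

  thresholds <- run_stage("threshold", {
    rows <- list()
    for (oc in config$outcomes) {
      for (g in c(levels(groups), "total")) {
        d <- if (g == "total") analysis else analysis[groups == g, ,
                                                      drop = FALSE]
        tf <- try(find_inflection(d, exposure = "mean_hba1c", outcome = oc,
                                  covariates = cov,
                                  grid_step = config$grid_step),
                  silent = TRUE)
        if (inherits(tf, "try-error")) {
          if (g == "total") stop(attr(tf, "condition"))
          # sparse group cell: report an empty (inestimable) row
          rows[[paste(oc, g)]] <- data.frame(
            outcome = oc, group = g, hr_linear = NA_real_,
            hr_linear_low = NA_real_, hr_linear_high = NA_real_,
            p_linear = NA_real_, inflection_k = NA_real_,
            k_ci_low = NA_real_, k_ci_high = NA_real_,
            hr_below = NA_real_, hr_below_low = NA_real_,
            hr_below_high = NA_real_, p_below = NA_real_,
            hr_above = NA_real_, hr_above_low = NA_real_,
            hr_above_high = NA_real_, p_above = NA_real_,
            p_curvature = NA_real_, events_below = NA_integer_,
            events_above = NA_integer_, sparse_below = TRUE,
            sparse_above = TRUE, stringsAsFactors = FALSE)
          next
        }
        if (config$n_boot >= 200)
          tf <- bootstrap_inflection_ci(tf, d, n_boot = config$n_boot,
                                        seed = mix_seed(config$seed, 31L,
                                                        length(rows)),
                                        grid_step = config$boot_grid_step)
        rows[[paste(oc, g)]] <- data.frame(
          outcome = oc, group = g,
          hr_linear = tf$hr_linear$hr, hr_linear_low = tf$hr_linear$ci_low,
          hr_linear_high = tf$hr_linear$ci_high,
          p_linear = tf$hr_linear$p_value,
          inflection_k = tf$inflection_k,
          k_ci_low = if (!is.null(tf$k_ci)) tf$k_ci[1] else NA_real_,
          k_ci_high = if (!is.null(tf$k_ci)) tf$k_ci[2] else NA_real_,
          hr_below = tf$hr_below$hr, hr_below_low = tf$hr_below$ci_low,
          hr_below_high = tf$hr_below$ci_high,
          p_below = tf$hr_below$p_value,
          hr_above = tf$hr_above$hr, hr_above_low = tf$hr_above$ci_low,
          hr_above_high = tf$hr_above$ci_high,
          p_above = tf$hr_above$p_value,
          p_curvature = tf$p_curvature,
          events_below = tf$events_below, events_above = tf$events_above,
          sparse_below = tf$sparse_below, sparse_above = tf$sparse_above,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })

  curves <- run_stage("smooth_curve", {
    rows <- list()
    for (oc in config$outcomes) {
      for (g in c("total", levels(groups))) {
        d <- if (g == "total") analysis else analysis[groups == g, ,
                                                      drop = FALSE]
        cr <- try(fit_smooth_hr(d, exposure = "mean_hba1c", outcome = oc,
                                covariates = cov, df = config$smooth_df),
                  silent = TRUE)
        if (inherits(cr, "try-error")) next  # group too small: skip curve
        rows[[paste(oc, g)]] <- cbind(outcome = oc, group = g,
                                      curve_report(cr))
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })

  manifest <- run_stage("manifest", {
    vm <- attr(metrics, "vim_model")
    list(package = "glycvar",
         version = as.character(utils::packageVersion("glycvar")),
         seed = config$seed,
         config_hash = config_hash(config),
         n_input = n_input,
         n_excluded = nrow(elig$exclusions),
         n_included = nrow(elig$patients),
         exclusion_reasons = as.list(table(elig$exclusions$reason)),
         chosen_k = clus$chosen_k,
         vim_exponent = vm$exponent_x,
         vim_agreement = clus$vim_agreement,
         outcomes = config$outcomes,
         simulated = is.null(config$visits))
  })

  structure(list(metrics = metrics, assignments = clus$assignments,
                 validation = clus$validation, group_summary = group_summary,
                 treatment_effects = treatment_effects,
                 thresholds = thresholds, curves = curves,
                 exclusions = elig$exclusions, manifest = manifest),
            class = "gv_report")
}

standardize_features <- function(x, scale) {
  if (scale == "zscore") standardize(x) else as.matrix(x)
}

#' @export
print.gv_report <- function(x, ...) {
  cat("Glycemic-variability analysis report\n")
  cat("  included:", x$manifest$n_included, "of", x$manifest$n_input,
      "patients (", x$manifest$n_excluded, "excluded )\n")
  cat("\nGroup summary (K-means):\n")
  print(transform(x$group_summary[, c("group", "n", "pct", "hvs_mean",
                                      "sd_mean", "mace_pct", "death_pct")],
                  pct = round(pct, 1), hvs_mean = round(hvs_mean, 1),
                  sd_mean = round(sd_mean, 2), mace_pct = round(mace_pct, 1),
                  death_pct = round(death_pct, 1)))
  cat("\nStratified treatment hazard ratios:\n")
  te <- x$treatment_effects
  print(transform(te[, c("method", "outcome", "group", "hr", "ci_low",
                         "ci_high", "p_interaction")],
                  hr = round(hr, 2), ci_low = round(ci_low, 2),
                  ci_high = round(ci_high, 2),
                  p_interaction = signif(p_interaction, 2)))
  invisible(x)
}

#' Write a report bundle to delimited files
#'
#' Writes every table of a [run_full_analysis()] report as CSV plus the
#' manifest as JSON. Output is byte-stable for a fixed config.
#'
#' @param report a `gv_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("metrics", "assignments", "validation", "group_summary",
              "treatment_effects", "thresholds", "curves", "exclusions")
  for (tb in tables) {
    if (!is.null(report[[tb]]))
      write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# 32-bit FNV-1a hash of the deparsed config (pure double arithmetic)
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  mul32 <- function(a) {
    lo <- a %% 65536
    hi <- a %/% 65536
    (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  for (b in bytes) {
    lo8 <- h %% 256                       # bytes only touch the low 8 bits
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    h <- mul32(h)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
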