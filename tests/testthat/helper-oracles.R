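# Independent naive oracles used to cross-check the optimized implementations.

oracle_hvs <- function(v, denominator = "intervals", threshold = 0.5) {
  n <- length(v)
  cnt <- 0
  for (i in seq_len(n - 1)) if (abs(v[i + 1] - v[i]) > threshold) cnt <- cnt + 1
  100 * cnt / (if (denominator == "intervals") n - 1 else n)
}

oracle_sd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

oracle_mean <- function(v) sum(v) / length(v)

euc <- function(a, b) sqrt(sum((a - b)^2))

# O(n^2) double-loop silhouette
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sum(labels == own) == 1) { s[i] <- 0; next }
    a <- mean(sapply(which(labels == own & seq_len(n) != i),
                     function(j) euc(X[i, ], X[j, ])))
    b <- Inf
    for (cl in setdiff(unique(labels), own)) {
      d <- mean(sapply(which(labels == cl), function(j) euc(X[i, ], X[j, ])))
      b <- min(b, d)
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_davies_bouldin <- function(X, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  cent <- t(sapply(labs, function(l) colMeans(X[labels == l, , drop = FALSE])))
  s <- sapply(seq_len(k), function(i)
    mean(apply(X[labels == labs[i], , drop = FALSE], 1, euc, b = cent[i, ])))
  db <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) if (j != i)
      worst <- max(worst, (s[i] + s[j]) / euc(cent[i, ], cent[j, ]))
    db <- db + worst
  }
  db / k
}

oracle_calinski_harabasz <- function(X, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  n <- nrow(X)
  g <- colMeans(X)
  W <- 0; B <- 0
  for (l in labs) {
    pts <- X[labels == l, , drop = FALSE]
    ci <- colMeans(pts)
    for (r in seq_len(nrow(pts))) W <- W + sum((pts[r, ] - ci)^2)
    B <- B + nrow(pts) * sum((ci - g)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# Exhaustive-partition k-means optimum (first point's label fixed by symmetry)
brute_kmeans_obj <- function(X, k) {
  n <- nrow(X)
  grids <- c(list(1L), rep(list(seq_len(k)), n - 1))
  labs <- as.matrix(expand.grid(grids))
  best <- Inf
  for (r in seq_len(nrow(labs))) {
    l <- labs[r, ]
    obj <- 0
    for (j in unique(l)) {
      pts <- X[l == j, , drop = FALSE]
      ctr <- colMeans(pts)
      obj <- obj + sum(sweep(pts, 2, ctr, "-")^2)
    }
    if (obj < best) best <- obj
  }
  best
}

# small random gaussian-blob dataset
rand_blobs <- function(n, k, sep = 4, d = 2) {
  centers <- matrix(rnorm(k * d) * sep, k, d)
  lab <- sample.int(k, n, replace = TRUE)
  centers[lab, , drop = FALSE] + matrix(rnorm(n * d), n, d)
}

# cohort whose hazards carry no exposure / covariate / treatment effects
# beyond those supplied, for correctly-specified survival simulations
flat_effect_spec <- function(treat_lhr = c(0, 0, 0),
                             k = c(NA, NA, NA),
                             slope_below = c(0, 0, 0),
                             slope_above = slope_below) {
  list(mace = list(k = k, slope_below = slope_below,
                   slope_above = slope_above, treat_lhr = treat_lhr),
       death = list(k = k, slope_below = slope_below,
                    slope_above = slope_above, treat_lhr = treat_lhr),
       center = 7.5)
}

zero_covariates <- function() c(age = 0, female = 0, bmi = 0, sbp = 0,
                                egfr = 0, smoking = 0)

# cohort with a single volatility stratum and a known mortality breakpoint,
# no treatment or covariate effects: a correctly specified threshold target
kinked_cohort <- function(n, seed, k_true = 7.5, hr_below = 0.49,
                          hr_above = 1.57) {
  p <- cohort_params(
    n_patients = n, seed = seed,
    volatility_mixture = list(weight = 1, shock_sd = 0.5),
    effect_spec = list(
      mace = list(k = NA, slope_below = 0, slope_above = 0, treat_lhr = 0),
      death = list(k = k_true, slope_below = log(hr_below),
                   slope_above = log(hr_above), treat_lhr = 0),
      center = 7.5),
    covariate_lhr = zero_covariates(),
    baseline_log_hazard = c(mace = -3.55, death = -3.3))
  co <- generate_cohort(p)
  cbind(co$patients, mean_hba1c = co$truth$mean_hba1c)
}
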