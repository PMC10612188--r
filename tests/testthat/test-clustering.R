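test_that("standardization matches hand computation and is reproducible", {
  x <- matrix(c(0, 100), ncol = 1, dimnames = list(NULL, "hvs"))
  z <- standardize(x)
  expect_equal(unname(z[, 1]), c(-1, 1) / sqrt(2))
  # applying the stored scaling to already-standardized data is the identity
  z2 <- standardize(z, center = c(hvs = 0), scale = c(hvs = 1))
  expect_equal(unname(z2[, 1]), unname(z[, 1]), tolerance = 1e-12)
  expect_error(standardize(cbind(a = c(1, 2), b = c(3, 3))),
               "zero-spread feature column: b")
})

test_that("k-means solves separable 1-D configurations exactly", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  km <- kmeans_fit(X, 2, seed = 1)
  expect_equal(sort(km$centroids[, 1]), c(0.5, 10.5))
  expect_equal(km$objective, 1)  # 4 x 0.5^2
  expect_length(unique(km$assignments[1:2]), 1)
  expect_length(unique(km$assignments[3:4]), 1)
  # k = n: every point its own centroid, objective 0
  kn <- kmeans_fit(X, 4, seed = 1)
  expect_equal(kn$objective, 0)
  expect_error(kmeans_fit(X, 5, seed = 1), "exceeds")
})

test_that("k-medians uses L1 geometry and resists outliers", {
  X <- matrix(c(0, 1, 2, 100), ncol = 1)
  kmd <- kmedians_fit(X, 2, seed = 1)
  expect_equal(sort(kmd$centroids[, 1]), c(1, 100))
  expect_equal(kmd$objective, 2)  # |0-1| + |1-1| + |2-1| + 0
  expect_equal(kmedians_fit(X, 4, seed = 1)$objective, 0)
  # an extreme outlier drags the k-means centroid further than the k-medians
  Y <- matrix(c(0, 1, 2, 3, 40, 100, 101, 102), ncol = 1)
  km <- kmeans_fit(Y, 2, seed = 3)
  kd <- kmedians_fit(Y, 2, seed = 3)
  # both attach the 40 outlier to the low cluster; the mean moves to 9.2,
  # the median stays at 2
  expect_equal(min(kd$centroids[, 1]), 2)
  expect_gt(min(km$centroids[, 1]), min(kd$centroids[, 1]))
})

test_that("clustering is deterministic and its objective never increases", {
  set.seed(10)
  X <- rand_blobs(120, 3)
  a <- kmeans_fit(X, 3, seed = 9, n_init = 5)
  b <- kmeans_fit(X, 3, seed = 9, n_init = 5)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$centroids, b$centroids)
  expect_true(all(diff(a$objective_trace) <= 1e-9))
  d <- kmedians_fit(X, 3, seed = 9, n_init = 5)
  expect_true(all(diff(d$objective_trace) <= 1e-9))
})

test_that("k-means matches stats::kmeans on well-separated data", {
  set.seed(22)
  X <- rand_blobs(150, 3, sep = 6)
  mine <- kmeans_fit(X, 3, seed = 4, n_init = 20)
  ref <- stats::kmeans(X, 3, nstart = 20, iter.max = 100)
  expect_equal(mine$objective, ref$tot.withinss, tolerance = 1e-8)
})

test_that("quantile clustering follows the rank/tie rules", {
  expect_equal(quantile_clusters(1:9), rep(1:3, each = 3))
  expect_equal(as.integer(table(quantile_clusters(sample(seq(0.1, 1,
                                                             0.1))))),
               c(4L, 3L, 3L))
  expect_warning(g <- quantile_clusters(rep(5, 9)), "collapsed")
  expect_true(all(g == 1))
  expect_error(quantile_clusters(numeric(0)))
  # stable order under ties: tied values share one group
  g2 <- suppressWarnings(quantile_clusters(c(1, 2, 2, 2, 3, 4, 5, 6, 7)))
  expect_length(unique(g2[2:4]), 1)
})

test_that("cluster ordering maps labels by mean HVS and is label-invariant", {
  set.seed(5)
  hvs_vals <- c(rnorm(30, 70, 2), rnorm(30, 20, 2), rnorm(30, 45, 2))
  sd_vals <- c(rnorm(30, 1.1, 0.05), rnorm(30, 0.5, 0.05),
               rnorm(30, 0.8, 0.05))
  X <- cbind(hvs_vals, sd_vals)
  km <- kmeans_fit(standardize(X), 3, seed = 2)
  km <- order_clusters(km, hvs_vals)
  g <- cluster_groups(km)
  expect_equal(unname(tapply(hvs_vals, g, mean) |> order()), 1:3)
  # permuting label ids leaves the ordered grouping invariant
  perm <- c(2L, 3L, 1L)
  km2 <- km
  km2$assignments <- perm[km$assignments]
  km2$centroids <- km$centroids[order(perm), ]
  km2 <- order_clusters(km2, hvs_vals)
  expect_equal(cluster_groups(km2), g)
  km$k <- 4
  expect_error(order_clusters(km, hvs_vals), "k = 3")
})

test_that("select_k picks the planted number of blobs", {
  set.seed(31)
  X3 <- standardize(rbind(matrix(rnorm(120, 0, 0.3), ncol = 2),
                          matrix(rnorm(120, 5, 0.3), ncol = 2),
                          cbind(rnorm(60, 10, 0.3), rnorm(60, 0, 0.3))))
  s3 <- select_k(X3, 2:9, method = "kmeans", seed = 1, n_init = 10)
  expect_equal(s3$k, 3)
  expect_equal(s3$scores$k, 2:9)  # one row per candidate k
  X2 <- standardize(rbind(matrix(rnorm(150, 0, 0.3), ncol = 2),
                          matrix(rnorm(150, 6, 0.3), ncol = 2)))
  s2 <- select_k(X2, 2:9, method = "kmeans", seed = 1, n_init = 10)
  expect_equal(s2$k, 2)
})

test_that("equal volatility strata degrade cluster separation", {
  p_sep <- cohort_params(n_patients = 900, seed = 13)
  p_flat <- cohort_params(n_patients = 900, seed = 13,
                          volatility_mixture = list(
                            weight = c(0.45, 0.39, 0.16),
                            shock_sd = c(0.55, 0.55, 0.55)))
  sil <- sapply(list(p_sep, p_flat), function(p) {
    co <- generate_cohort(p)
    m <- compute_metrics(co$visits)
    X <- standardize(m[, c("hvs", "sd")])
    km <- kmeans_fit(X, 3, seed = 2, n_init = 10)
    silhouette_index(X, km$assignments)
  })
  expect_gt(sil[1], sil[2])
})
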