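#' Standardize a feature matrix
#'
#' Centers each column to mean 0 and scales it to unit sample SD, recording
#' the scaling so new data (or a re-application) can be transformed
#' identically. HVS spans 0-100 while the SD of HbA1c spans roughly 0-2, so
#' clustering on raw features would be dominated by HVS.
#'
#' @param x numeric matrix or data.frame of features (columns named).
#' @param center,scale optional previously stored scaling to apply instead of
#'   estimating from `x`.
#' @return numeric matrix with attributes `center` and `scale`.
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("standardize needs at least 2 rows")
  if (anyNA(x)) stop("features contain missing values")
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    bad <- which(scale <= 0 | !is.finite(scale))
    if (length(bad))
      stop("zero-spread feature column: ",
           paste(colnames(x)[bad], collapse = ", "))
  }
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

# squared Euclidean (l2) or absolute (l1) distances from points to centroids
point_centroid_dist <- function(x, centroids, metric) {
  k <- nrow(centroids)
  n <- nrow(x)
  D <- matrix(0, n, k)
  if (metric == "l2") {
    for (j in seq_len(k))
      D[, j] <- rowSums(sweep(x, 2, centroids[j, ], "-")^2)
  } else {
    for (j in seq_len(k))
      D[, j] <- rowSums(abs(sweep(x, 2, centroids[j, ], "-")))
  }
  D
}

# k-means++ style seeding (probability proportional to current distance)
seed_centroids <- function(x, k, metric) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- point_centroid_dist(x, x[idx[1], , drop = FALSE], metric)[, 1]
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, point_centroid_dist(x, x[idx[j], , drop = FALSE],
                                         metric)[, 1])
    }
  }
  x[idx, , drop = FALSE]
}

col_medians <- function(x) apply(x, 2, median)

# One Lloyd-style run from a given seeding. Assignment ties go to the lowest
# centroid index; empty clusters are re-seeded at the point farthest from its
# assigned centroid. Returns labels, centroids, objective and per-iteration
# objective trace (non-increasing).
lloyd_run <- function(x, k, metric, max_iter) {
  centroids <- seed_centroids(x, k, metric)
  labels_old <- rep(0L, nrow(x))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- point_centroid_dist(x, centroids, metric)
    labels <- max.col(-D, ties.method = "first")
    # empty-cluster repair
    for (rep_try in seq_len(k)) {
      sizes <- tabulate(labels, nbins = k)
      empties <- which(sizes == 0)
      if (!length(empties)) break
      dmin <- D[cbind(seq_len(nrow(x)), labels)]
      far <- which.max(dmin)
      centroids[empties[1], ] <- x[far, ]
      D <- point_centroid_dist(x, centroids, metric)
      labels <- max.col(-D, ties.method = "first")
    }
    trace <- c(trace, sum(D[cbind(seq_len(nrow(x)), labels)]))
    if (all(labels == labels_old)) break
    labels_old <- labels
    for (j in seq_len(k)) {
      pts <- x[labels == j, , drop = FALSE]
      centroids[j, ] <- if (metric == "l2") colMeans(pts) else col_medians(pts)
    }
    # objective after the update step (with fresh assignments' centroids)
    D2 <- point_centroid_dist(x, centroids, metric)
    trace <- c(trace, sum(D2[cbind(seq_len(nrow(x)), labels)]))
  }
  list(labels = labels, centroids = centroids,
       objective = trace[length(trace)], trace = trace, iter = it)
}

cluster_engine <- function(x, k, metric, seed, n_init, max_iter, method) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of points (", n, ")")
  if (anyNA(x)) stop("features contain missing values")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      run <- lloyd_run(x, k, metric, max_iter)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
  })
  structure(list(method = method, k = k, centroids = best$centroids,
                 assignments = best$labels, objective = best$objective,
                 objective_trace = best$trace, seed = seed, n_init = n_init,
                 scaling = list(center = attr(x, "center"),
                                scale = attr(x, "scale")),
                 order_map = NULL),
            class = "cluster_model")
}

#' K-means clustering (Lloyd's algorithm, k-means++ seeding)
#'
#' Partitions points into `k` clusters minimizing the within-cluster sum of
#' squared Euclidean distances. Runs `n_init` seeded restarts and keeps the
#' best objective; each run iterates assignment/update steps to an exact
#' assignment fixpoint (or `max_iter`). The within-run objective is
#' non-increasing across iterations.
#'
#' @param x numeric matrix (typically from [standardize()]).
#' @param k number of clusters.
#' @param seed RNG seed; fixed seed + `n_init` gives an identical model.
#' @param n_init number of random restarts.
#' @param max_iter iteration cap per restart.
#' @return object of class `cluster_model` with `centroids`, `assignments`
#'   (labels 1..k), `objective` and the per-iteration `objective_trace`.
#' @export
kmeans_fit <- function(x, k, seed = 1, n_init = 20, max_iter = 300) {
  cluster_engine(x, k, "l2", seed, n_init, max_iter, "kmeans")
}

#' K-medians clustering
#'
#' As [kmeans_fit()] but with L1 (one-norm) assignment distances and
#' coordinate-wise median centroid updates; the objective is the total L1
#' deviation, making the partition robust to outlying patients.
#'
#' @inheritParams kmeans_fit
#' @return a `cluster_model` (method `"kmedians"`).
#' @export
kmedians_fit <- function(x, k, seed = 1, n_init = 20, max_iter = 300) {
  cluster_engine(x, k, "l1", seed, n_init, max_iter, "kmedians")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("%s model: k = %d, n = %d, objective = %.4f\n", x$method, x$k,
              length(x$assignments), x$objective))
  sizes <- tabulate(x$assignments, nbins = x$k)
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  if (!is.null(x$order_map))
    cat("  ordering:", paste(names(x$order_map), x$order_map, sep = "->",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Quantile (tertile) clustering on a single metric
#'
#' Ranks patients on one variability metric and cuts the ranks into
#' `n_groups` nearly equal groups (sizes differ by at most 1, plus spillover
#' from ties: patients with identical metric values always share a group,
#' taking the group of the first tied member in stable order).
#'
#' @param values numeric metric, one per patient.
#' @param n_groups number of groups (default 3: low/medium/high).
#' @return integer group labels 1..n_groups (1 = lowest metric). A warning is
#'   emitted if ties collapse any group to empty.
#' @export
quantile_clusters <- function(values, n_groups = 3) {
  n <- length(values)
  if (n == 0) stop("no values to cluster")
  if (n < n_groups) stop("need at least ", n_groups, " patients")
  if (anyNA(values)) stop("values contain missing entries")
  r <- rank(values, ties.method = "first")
  g <- floor((r - 1) * n_groups / n) + 1L
  # tied values share the group of their first (stable-order) member
  g <- as.integer(ave(g, match(values, values), FUN = min))
  if (length(unique(g)) < n_groups)
    warning("ties collapsed ", n_groups - length(unique(g)),
            " quantile group(s)")
  g
}

#' Order clusters as low / medium / high variability
#'
#' Sorts the k = 3 cluster labels by their within-cluster mean HVS and maps
#' them to `"low"`, `"medium"`, `"high"`.
#'
#' @param model a `cluster_model` with k = 3.
#' @param hvs per-patient HVS values aligned with `model$assignments`.
#' @return the model, with `order_map` set (named character vector
#'   label -> group).
#' @export
order_clusters <- function(model, hvs) {
  if (model$k != 3) stop("ordering to low/medium/high requires k = 3")
  if (length(hvs) != length(model$assignments))
    stop("hvs length must match assignments")
  m <- tapply(hvs, model$assignments, mean)
  ord <- order(m)
  map <- character(3)
  map[as.integer(names(m))[ord]] <- c("low", "medium", "high")
  names(map) <- seq_len(3)
  model$order_map <- map
  model
}

#' Cluster group factor (low/medium/high) for a fitted, ordered model
#' @param model an ordered `cluster_model` (see [order_clusters()]).
#' @return factor with levels low, medium, high.
#' @export
cluster_groups <- function(model) {
  if (is.null(model$order_map)) stop("model has no order_map; run order_clusters()")
  factor(unname(model$order_map[model$assignments]),
         levels = c("low", "medium", "high"))
}

#' Internal validation scores across a range of k
#'
#' Fits the requested clustering for each k and computes the
#' Calinski-Harabasz, Davies-Bouldin and silhouette indices. The selected k
#' maximizes the mean rank of (silhouette, -Davies-Bouldin) -- i.e. the two
#' combinable indices agree on compact, well-separated clusters; the full
#' score table is always returned. Ties go to the smallest k.
#'
#' @param x numeric feature matrix (standardized).
#' @param k_range candidate cluster counts (within 2..9).
#' @param method `"kmeans"` or `"kmedians"`.
#' @param seed,n_init passed to the fitting routine.
#' @return list with `scores` (data.frame: k, calinski_harabasz,
#'   davies_bouldin, silhouette), `k` (chosen), and `models` (fitted models
#'   indexed by k).
#' @export
select_k <- function(x, k_range = 2:9, method = c("kmeans", "kmedians"),
                     seed = 1, n_init = 20) {
  method <- match.arg(method)
  if (any(k_range < 2) || any(k_range > nrow(x) - 1))
    stop("k_range must lie within 2 .. n-1")
  fitter <- if (method == "kmeans") kmeans_fit else kmedians_fit
  models <- list()
  scores <- data.frame(k = as.integer(k_range), calinski_harabasz = NA_real_,
                       davies_bouldin = NA_real_, silhouette = NA_real_)
  D <- as.matrix(stats::dist(x))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- fitter(x, k, seed = mix_seed(seed, 11L, k), n_init = n_init)
    models[[as.character(k)]] <- fit
    scores$calinski_harabasz[i] <- calinski_harabasz_index(x, fit$assignments)
    scores$davies_bouldin[i] <- davies_bouldin_index(x, fit$assignments)
    scores$silhouette[i] <- silhouette_index(x, fit$assignments, dist_matrix = D)
  }
  comb <- rank(scores$silhouette) + rank(-scores$davies_bouldin)
  chosen <- scores$k[which.max(comb)]
  list(scores = scores, k = chosen, models = models)
}
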