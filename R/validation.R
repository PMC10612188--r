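# Internal clustering validation indices, implemented from first principles
# on Euclidean distances. All three are invariant to label permutation and to
# rigid rotation of the features.

check_labels <- function(x, labels) {
  if (nrow(x) != length(labels)) stop("labels must match rows of x")
  labs <- sort(unique(labels))
  k <- length(labs)
  list(labs = labs, k = k, n = nrow(x))
}

#' Silhouette index
#'
#' Mean over all points of `(b - a) / max(a, b)` where `a` is the mean
#' distance to the point's own cluster (excluding itself) and `b` the
#' smallest mean distance to any other cluster. A singleton point's
#' silhouette is defined as 0. Requires `2 <= k <= n - 1`.
#'
#' @param x numeric matrix of features.
#' @param labels cluster labels.
#' @param dist_matrix optional precomputed `as.matrix(dist(x))` (reused
#'   across k when scanning).
#' @return silhouette score in [-1, 1].
#' @export
silhouette_index <- function(x, labels, dist_matrix = NULL) {
  info <- check_labels(x, labels)
  if (info$k < 2 || info$k > info$n - 1)
    stop("silhouette requires 2 <= k <= n-1 clusters")
  D <- if (is.null(dist_matrix)) as.matrix(stats::dist(x)) else dist_matrix
  f <- factor(labels, levels = info$labs)
  ind <- stats::model.matrix(~ f - 1)           # n x k membership
  sums <- D %*% ind                             # distance sums to each cluster
  sizes <- colSums(ind)
  own <- as.integer(f)
  a_den <- sizes[own] - 1
  a <- ifelse(a_den > 0, sums[cbind(seq_len(info$n), own)] / a_den, NA)
  meanD <- sweep(sums, 2, sizes, "/")
  meanD[cbind(seq_len(info$n), own)] <- Inf
  b <- apply(meanD, 1, min)
  s <- ifelse(is.na(a), 0, (b - a) / pmax(a, b))
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst ratio `(s_i + s_j) / d(c_i, c_j)`, where
#' `s_i` is the mean Euclidean distance of cluster i's points to their
#' centroid and `d` the distance between centroids. Lower is better.
#' Coincident centroids make the ratio undefined and raise an error.
#'
#' @inheritParams silhouette_index
#' @return Davies-Bouldin score (>= 0).
#' @export
davies_bouldin_index <- function(x, labels) {
  info <- check_labels(x, labels)
  if (info$k < 2) stop("Davies-Bouldin requires k >= 2")
  cent <- matrix(0, info$k, ncol(x))
  s <- numeric(info$k)
  for (i in seq_len(info$k)) {
    pts <- x[labels == info$labs[i], , drop = FALSE]
    cent[i, ] <- colMeans(pts)
    s[i] <- mean(sqrt(rowSums(sweep(pts, 2, cent[i, ], "-")^2)))
  }
  dc <- as.matrix(stats::dist(cent))
  if (any(dc[upper.tri(dc)] < 1e-12))
    stop("coincident cluster centroids: Davies-Bouldin undefined")
  R <- outer(s, s, "+") / dc
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `[tr(B)/(k-1)] / [tr(W)/(n-k)]`; higher is better. Errors when the
#' within-cluster dispersion is exactly zero (duplicate points only).
#'
#' @inheritParams silhouette_index
#' @return Calinski-Harabasz score (>= 0).
#' @export
calinski_harabasz_index <- function(x, labels) {
  info <- check_labels(x, labels)
  if (info$k < 2) stop("Calinski-Harabasz requires k >= 2")
  overall <- colMeans(x)
  W <- 0; B <- 0
  for (i in seq_len(info$k)) {
    pts <- x[labels == info$labs[i], , drop = FALSE]
    ci <- colMeans(pts)
    W <- W + sum(sweep(pts, 2, ci, "-")^2)
    B <- B + nrow(pts) * sum((ci - overall)^2)
  }
  if (W <= 0) stop("zero within-cluster dispersion: index undefined")
  (B / (info$k - 1)) / (W / (info$n - info$k))
}
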