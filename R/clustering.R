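#' Agglomerative clustering of a similarity matrix
#'
#' Hierarchical agglomeration with average linkage (configurable) on the
#' distance `D = 1 - M`, where `M` is a similarity in `[0, 1]`. Learned
#' similarity matrices are used as-is; a `kernel_matrix` (range
#' `[0, tanh(1)]`) is rescaled to `[0, 1]` by `1/tanh(1)` first. The
#' dendrogram is cut at `k` clusters. The procedure is deterministic given
#' `M`.
#'
#' @param m square symmetric similarity matrix (learned similarity or
#'   `kernel_matrix`).
#' @param k number of clusters (`1 <= k <= n`; 1 and n are degenerate but
#'   allowed).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return A `clustering_result`: list with integer `labels` in `0..k-1`
#'   named by cell id, `k`, `method`, `k_source`, `seed`.
#' @examples
#' m <- diag(4); m[1, 2] <- m[2, 1] <- 1; m[3, 4] <- m[4, 3] <- 1
#' agglomerative_from_similarity(m, 2)$labels
#' @export
agglomerative_from_similarity <- function(m, k,
                                          linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  ids <- rownames(m)
  m <- as_unit_similarity(m)
  n <- nrow(m)
  check_that(k >= 1 && k <= n, sprintf("`k` must be in [1, %d]", n))
  d <- 1 - m
  hc <- hclust(stats::as.dist(d), method = linkage)
  labels <- cutree(hc, k = k) - 1L
  names(labels) <- ids %||% paste0("cell_", seq_len(n))
  clustering_result(labels, k, "AG", "given", seed = NA_integer_, tree = hc)
}

clustering_result <- function(labels, k, method, k_source, seed, tree = NULL) {
  structure(list(labels = labels, k = as.integer(k), method = method,
                 k_source = k_source, seed = seed, tree = tree),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s, k = %d (%s), %d cells\n",
              x$method, x$k, x$k_source, length(x$labels)))
  print(table(x$labels))
  invisible(x)
}

# k-means++ seeding: D^2-weighted, deterministic under the current RNG state
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = probs)
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(x[idx, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' K-means and spectral clustering variants
#'
#' The two alternative partitioners of the clustering stage. `KM` runs
#' Lloyd-type k-means with k-means++ initialisation on the rows of the input
#' (a similarity matrix treated as per-cell feature rows, or an embedding).
#' `SC` treats the input as an affinity matrix and performs normalised-cut
#' spectral clustering: the k leading eigenvectors of the symmetrically
#' normalised affinity `D^{-1/2} M D^{-1/2}` are row-normalised and
#' partitioned by k-means.
#'
#' @param x numeric matrix — per-cell feature rows for `KM`, a square
#'   affinity for `SC`. `kernel_matrix` inputs are rescaled to `[0, 1]`.
#' @param k number of clusters.
#' @param method `"KM"` or `"SC"`.
#' @param seed integer seed for the k-means initialisation.
#' @return A `clustering_result`.
#' @export
cluster_variants <- function(x, k, method = c("KM", "SC"), seed = 0) {
  method <- match.arg(method)
  ids <- rownames(x)
  check_that(k <= nrow(x), sprintf("`k` (%d) exceeds the number of cells (%d)",
                                   k, nrow(x)))
  check_that(k >= 1, "`k` must be >= 1")
  if (inherits(x, "kernel_matrix")) x <- unclass(x) / TANH1
  x <- unclass(x)
  feats <- if (method == "SC") spectral_embedding(x, k) else x
  labels <- with_seed(seed, {
    centers <- kmeanspp_centers(feats, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    km <- suppressWarnings(
      kmeans(feats, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    km$cluster
  })
  labels <- as.integer(factor(labels)) - 1L
  names(labels) <- ids %||% paste0("cell_", seq_len(nrow(x)))
  clustering_result(labels, length(unique(labels)), method, "given", seed)
}

spectral_embedding <- function(m, k) {
  check_that(nrow(m) == ncol(m), "spectral clustering needs a square affinity")
  m <- (m + t(m)) / 2
  deg <- pmax(rowSums(m), .Machine$double.eps)
  dm <- 1 / sqrt(deg)
  lsym <- m * tcrossprod(dm)                 # D^-1/2 M D^-1/2
  ev <- eigen(lsym, symmetric = TRUE)
  u <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(u^2))
  u / pmax(rn, .Machine$double.eps)
}

#' Mean silhouette width of a partition under a precomputed distance
#'
#' For each cell, `a` is the mean distance to its own cluster (excluding
#' itself) and `b` the smallest mean distance to another cluster; the
#' silhouette is `(b - a) / max(a, b)`, defined as 0 for singletons and when
#' `a == b == 0`.
#'
#' @param d square distance matrix.
#' @param labels cluster assignment vector.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
mean_silhouette <- function(d, labels) {
  n <- nrow(d)
  check_that(length(labels) == n, "labels/distance size mismatch")
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) return(0)
  sizes <- tabulate(labels, k)
  # mean distance from every cell to every cluster, n x k
  agg <- sapply(seq_len(k), function(cl) rowSums(d[, labels == cl, drop = FALSE]))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    cl <- labels[i]
    if (sizes[cl] == 1) { sil[i] <- 0; next }
    a <- agg[i, cl] / (sizes[cl] - 1)
    b <- min((agg[i, -cl] / sizes[-cl]))
    m <- max(a, b)
    sil[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(sil)
}

#' Estimate the number of clusters by a silhouette sweep
#'
#' Cuts the average-linkage dendrogram of `D = 1 - M` at every
#' `k in k_min..k_max` and returns the `k` with the largest mean silhouette
#' width under the same distance. Ties break toward the smaller `k`.
#'
#' @param m similarity matrix (learned similarity or `kernel_matrix`).
#' @param k_min smallest candidate (default 2).
#' @param k_max largest candidate (default `min(15, n - 1)`).
#' @return The estimated number of clusters.
#' @export
estimate_num_clusters <- function(m, k_min = 2, k_max = NULL) {
  msim <- as_unit_similarity(m)
  n <- nrow(msim)
  check_that(n >= 4, "cluster-number estimation needs at least 4 cells")
  k_max <- k_max %||% min(15L, n - 1L)
  check_that(k_min >= 2 && k_min < k_max && k_max <= n - 1,
             sprintf("need 2 <= k_min < k_max <= %d", n - 1))
  d <- 1 - msim
  hc <- hclust(stats::as.dist(d), method = "average")
  ks <- k_min:k_max
  scores <- vapply(ks, function(k) mean_silhouette(d, cutree(hc, k)), numeric(1))
  ks[which.max(scores)]  # which.max takes the first maximum: smaller k wins ties
}
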