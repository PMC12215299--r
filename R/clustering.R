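#' Distance between two vectors
#'
#' Standard metrics used throughout the clustering module. Cosine distance is
#' `1 - cosine similarity`; Jaccard distance binarizes both vectors
#' (nonzero -> 1) and returns `1 - |intersection| / |union|` (0 when both
#' vectors are all-zero after binarization).
#'
#' @param x,y Numeric vectors of equal length.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"cosine"`, `"jaccard"`.
#' @return A non-negative scalar distance.
#' @examples
#' point_distance(c(0, 0), c(3, 4))            # 5
#' point_distance(c(1, 1, 0), c(1, 0, 1), "jaccard")  # 2/3
#' @export
point_distance <- function(x, y, metric = c("euclidean", "manhattan",
                                            "cosine", "jaccard")) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    cosine = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 && ny == 0) {
        stop("cosine distance is undefined for two zero vectors", call. = FALSE)
      }
      if (nx == 0 || ny == 0) return(1)
      1 - sum(x * y) / (nx * ny)
    },
    jaccard = {
      bx <- x != 0; by <- y != 0
      u <- sum(bx | by)
      if (u == 0) return(0)
      1 - sum(bx & by) / u
    }
  )
}

#' Pairwise distance matrix for a point set
#'
#' @param points A data frame or matrix, one point per row.
#' @inheritParams point_distance
#' @return A symmetric n x n matrix of distances.
#' @export
pairwise_distances <- function(points, metric = c("euclidean", "manhattan",
                                                  "cosine", "jaccard")) {
  metric <- match.arg(metric)
  m <- point_matrix(points)
  if (metric %in% c("euclidean", "manhattan")) {
    return(as.matrix(stats::dist(m, method = metric)))
  }
  if (metric == "jaccard") {
    b <- m != 0
    d <- as.matrix(stats::dist(b, method = "binary"))
    # dist() leaves NaN for all-zero pairs; both-empty sets are identical
    d[is.nan(d)] <- 0
    return(d)
  }
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0) && sum(norms == 0) > 1) {
    stop("cosine distance is undefined for two zero vectors", call. = FALSE)
  }
  sim <- (m %*% t(m)) / outer(norms, norms)
  sim[is.nan(sim)] <- 0
  d <- 1 - sim
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Z-score standardize every column of a point set
#'
#' Centers each column on its mean and scales it to unit standard deviation,
#' using the population convention (divisor n).
#'
#' @param points A data frame or matrix; a `cluster` column, if present, is
#'   passed through untouched.
#' @return A tibble of the same shape with attribute `scaling = "z-score
#'   (population sd)"`.
#' @export
standardize_points <- function(points) {
  df <- tibble::as_tibble(as.data.frame(points), .name_repair = "minimal")
  labels <- df[["cluster"]]
  df[["cluster"]] <- NULL
  for (nm in names(df)) {
    v <- df[[nm]]
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    if (sd_pop == 0) {
      stop("column '", nm, "' is constant and cannot be standardized",
           call. = FALSE)
    }
    df[[nm]] <- (v - mu) / sd_pop
  }
  if (!is.null(labels)) df$cluster <- labels
  attr(df, "scaling") <- "z-score (population sd)"
  df
}

# squared euclidean distances from every point to every centroid
sq_dist_to_centroids <- function(m, centroids) {
  outer(rowSums(m^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(m)), rowSums(centroids^2)) -
    2 * m %*% t(centroids)
}

kmeans_pp_init <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((m - matrix(m[centers[1], ], n, ncol(m), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) == 0) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    nd <- rowSums((m - matrix(m[centers[j], ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  m[centers, , drop = FALSE]
}

lloyd_once <- function(m, k, max_iter, tol) {
  centroids <- kmeans_pp_init(m, k)
  n <- nrow(m)
  trace <- numeric(0)
  labels <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist_to_centroids(m, centroids)
    labels <- max.col(-d2, ties.method = "first")  # ties -> lowest centroid index
    # re-seed empty clusters to the point farthest from its assigned centroid
    for (j in which(tabulate(labels, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), labels)])
      centroids[j, ] <- m[far, ]
      d2[, j] <- rowSums((m - matrix(m[far, ], n, ncol(m), byrow = TRUE))^2)
      labels <- max.col(-d2, ties.method = "first")
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), labels)]))
    new_centroids <- centroids
    for (j in seq_len(k)) {
      new_centroids[j, ] <- colMeans(m[labels == j, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centroids - centroids)^2)))
    centroids <- new_centroids
    if (shift < tol) break
  }
  d2 <- sq_dist_to_centroids(m, centroids)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum((m - centroids[labels, , drop = FALSE])^2)
  list(labels = labels, centroids = centroids, inertia = inertia,
       trace = c(trace, inertia), iterations = iter)
}

#' Seeded k-means clustering (Lloyd's algorithm, k-means++ start)
#'
#' Assignment ties break toward the lowest centroid index; an empty cluster is
#' re-seeded to the point farthest from its current centroid; iteration stops
#' when the largest centroid shift drops below `tol`. The within-cluster sum
#' of squared euclidean distances (inertia) is recorded after every
#' assignment step.
#'
#' @param points A data frame or matrix of points (a `cluster` column is
#'   ignored).
#' @param k Number of clusters, `2 <= k <= n` (`k = n` is allowed and gives
#'   zero inertia).
#' @param seed Integer seed for the k-means++ initialization; `NULL` uses the
#'   current RNG state.
#' @param max_iter,tol Lloyd iteration controls.
#' @param nstart Number of independent restarts; the lowest-inertia fit wins.
#' @return A `pedo_kmeans` object: list with `labels` (1..k), `centroids`,
#'   `inertia`, `trace` (inertia per iteration), `iterations`, `k`, `seed`.
#' @export
kmeans_cluster <- function(points, k, seed = NULL, max_iter = 100L,
                           tol = 1e-8, nstart = 1L) {
  m <- point_matrix(points)
  n <- nrow(m)
  if (k < 2 || k > n) stop("`k` must satisfy 2 <= k <= n", call. = FALSE)
  run_all <- function() {
    fits <- lapply(seq_len(nstart), function(i) lloyd_once(m, k, max_iter, tol))
    fits[[which.min(vapply(fits, `[[`, numeric(1), "inertia"))]]
  }
  fit <- if (is.null(seed)) run_all() else withr::with_seed(as.integer(seed), run_all())
  structure(
    c(fit, list(k = as.integer(k), seed = seed)),
    class = "pedo_kmeans"
  )
}

#' @export
print.pedo_kmeans <- function(x, ...) {
  cat(sprintf("<pedo_kmeans> k = %d, n = %d, inertia = %.6g (%d iterations)\n",
              x$k, length(x$labels), x$inertia, x$iterations))
  invisible(x)
}

#' Inertia versus k (elbow diagnostic)
#'
#' Runs best-of-`restarts` k-means for every k in `k_range`. One restart per k
#' is warm-started from the previous k's best centroids plus the point
#' farthest from them, which guarantees the curve is non-increasing in k.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Integer vector of cluster counts, each in `[2, n]`.
#' @param restarts Random restarts per k (default 5).
#' @return A tibble of class `pedo_elbow` with columns `k` and `inertia`.
#' @export
elbow_curve <- function(points, k_range, seed = NULL, restarts = 5L) {
  m <- point_matrix(points)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > nrow(m))) {
    stop("`k_range` must lie within [2, n]", call. = FALSE)
  }
  run <- function() {
    prev <- NULL
    out <- numeric(length(k_range))
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      fit <- lloyd_like_best(m, k, restarts, prev)
      out[i] <- fit$inertia
      prev <- fit
    }
    out
  }
  inertias <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  structure(tibble::tibble(k = k_range, inertia = inertias),
            class = c("pedo_elbow", class(tibble::tibble())))
}

lloyd_like_best <- function(m, k, restarts, prev) {
  fits <- lapply(seq_len(restarts), function(i) lloyd_once(m, k, 100L, 1e-8))
  if (!is.null(prev) && nrow(prev$centroids) < k) {
    centroids <- prev$centroids
    while (nrow(centroids) < k) {
      d2 <- sq_dist_to_centroids(m, centroids)
      far <- which.max(apply(d2, 1, min))
      centroids <- rbind(centroids, m[far, ])
    }
    fits <- c(fits, list(lloyd_from(m, centroids, 100L, 1e-8)))
  }
  fits[[which.min(vapply(fits, `[[`, numeric(1), "inertia"))]]
}

lloyd_from <- function(m, centroids, max_iter, tol) {
  n <- nrow(m); k <- nrow(centroids)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist_to_centroids(m, centroids)
    labels <- max.col(-d2, ties.method = "first")
    for (j in which(tabulate(labels, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), labels)])
      centroids[j, ] <- m[far, ]
      d2 <- sq_dist_to_centroids(m, centroids)
      labels <- max.col(-d2, ties.method = "first")
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), labels)]))
    new_centroids <- centroids
    for (j in seq_len(k)) {
      new_centroids[j, ] <- colMeans(m[labels == j, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centroids - centroids)^2)))
    centroids <- new_centroids
    if (shift < tol) break
  }
  d2 <- sq_dist_to_centroids(m, centroids)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum((m - centroids[labels, , drop = FALSE])^2)
  list(labels = labels, centroids = centroids, inertia = inertia,
       trace = c(trace, inertia), iterations = iter)
}

#' Agglomerative hierarchical clustering
#'
#' Bottom-up merging with the standard linkages. Ward linkage requires the
#' euclidean metric.
#'
#' @inheritParams pairwise_distances
#' @param linkage `"single"`, `"complete"`, `"average"`, or `"ward"`.
#' @return A `pedo_dendrogram`: list with `merges` (tibble `a`, `b`, `height`,
#'   `size`; negative ids are leaves as in [stats::hclust()]), `linkage`,
#'   `metric`, `n`, and the underlying `hclust` object.
#' @export
agglomerative_cluster <- function(points,
                                  linkage = c("single", "complete",
                                              "average", "ward"),
                                  metric = c("euclidean", "manhattan",
                                             "cosine", "jaccard")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  m <- point_matrix(points)
  if (nrow(m) < 2) stop("need at least two points", call. = FALSE)
  if (linkage == "ward" && metric != "euclidean") {
    stop("ward linkage requires the euclidean metric", call. = FALSE)
  }
  d <- stats::as.dist(pairwise_distances(m, metric))
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(d, method = method)
  merges <- tibble::tibble(
    a = hc$merge[, 1], b = hc$merge[, 2], height = hc$height,
    size = vapply(seq_len(nrow(hc$merge)), function(i) {
      cluster_size_at(hc$merge, i)
    }, integer(1))
  )
  structure(
    list(merges = merges, linkage = linkage, metric = metric,
         n = nrow(m), hclust = hc),
    class = "pedo_dendrogram"
  )
}

cluster_size_at <- function(merge, i) {
  sz <- function(id) if (id < 0) 1L else cluster_size_at(merge, id)
  sz(merge[i, 1]) + sz(merge[i, 2])
}

#' @export
print.pedo_dendrogram <- function(x, ...) {
  cat(sprintf("<pedo_dendrogram> n = %d, linkage = %s, metric = %s\n",
              x$n, x$linkage, x$metric))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' @param dendrogram A `pedo_dendrogram`.
#' @param k Number of clusters.
#' @return Integer labels in `1..k`.
#' @export
cut_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "pedo_dendrogram"))
  unname(stats::cutree(dendrogram$hclust, k = k))
}

check_labels <- function(labels, n) {
  labels <- as.integer(as.factor(labels))
  if (length(labels) != n) stop("one label per point is required", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("validity indices need at least 2 clusters", call. = FALSE)
  }
  labels
}

#' Silhouette widths and mean silhouette score
#'
#' For point i, `a(i)` is its mean distance to the other members of its
#' cluster and `b(i)` the smallest mean distance to any other cluster;
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Members of singleton clusters get
#' `s(i) = 0`.
#'
#' @param points A data frame or matrix of points.
#' @param labels Cluster labels, one per point (any coding; `NULL` uses the
#'   `cluster` column of `points`).
#' @inheritParams point_distance
#' @return A list with `widths` (tibble `point`, `cluster`, `width`) and
#'   `mean` (the mean silhouette score, in `[-1, 1]`).
#' @export
silhouette_score <- function(points, labels = NULL,
                             metric = c("euclidean", "manhattan",
                                        "cosine", "jaccard")) {
  metric <- match.arg(metric)
  m <- point_matrix(points)
  if (is.null(labels) && is.data.frame(points)) labels <- points[["cluster"]]
  labels <- check_labels(labels, nrow(m))
  d <- pairwise_distances(m, metric)
  ks <- sort(unique(labels))
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1L)
    b <- min(vapply(ks[ks != labels[i]],
                    function(kk) mean(d[i, labels == kk]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(widths = tibble::tibble(point = seq_len(n), cluster = labels, width = s),
       mean = mean(s))
}

cluster_centroids <- function(m, labels) {
  ks <- sort(unique(labels))
  out <- matrix(0, length(ks), ncol(m))
  for (i in seq_along(ks)) {
    out[i, ] <- colMeans(m[labels == ks[i], , drop = FALSE])
  }
  out
}

#' Davies-Bouldin index
#'
#' `DBI = (1/k) * sum_i max_{j != i} (R_i + R_j) / d(c_i, c_j)` with cluster
#' centroids `c_i` (means) and `R_i` the mean euclidean distance of members to
#' their centroid. Lower is better.
#'
#' @inheritParams silhouette_score
#' @return A non-negative scalar.
#' @export
davies_bouldin <- function(points, labels = NULL) {
  m <- point_matrix(points)
  if (is.null(labels) && is.data.frame(points)) labels <- points[["cluster"]]
  labels <- check_labels(labels, nrow(m))
  ks <- sort(unique(labels))
  cen <- cluster_centroids(m, labels)
  if (anyDuplicated(cen) > 0) {
    stop("coincident cluster centroids: Davies-Bouldin is undefined", call. = FALSE)
  }
  radius <- vapply(seq_along(ks), function(i) {
    mem <- m[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((mem - matrix(cen[i, ], nrow(mem), ncol(m), byrow = TRUE))^2)))
  }, numeric(1))
  cen_d <- as.matrix(stats::dist(cen))
  k <- length(ks)
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (radius[i] + radius[j]) / cen_d[i, j], numeric(1)))
  }, numeric(1)))
}

#' Dunn index (standard and summation variants)
#'
#' The standard Dunn index is the minimum between-cluster point distance
#' divided by the maximum intra-cluster diameter (higher is better); when all
#' diameters are zero it is `Inf`, returned with a warning. The `"paper"`
#' variant evaluates the summation form
#' `(1/k) * sum_i max_{j != i} (r_i + r_j) / d(c_i, c_j)` with `r_i` the mean
#' member-to-centroid distance — structurally the Davies-Bouldin expression;
#' both are carried in every [cluster_quality()] report.
#'
#' @inheritParams silhouette_score
#' @param variant `"standard"` or `"paper"`.
#' @return A non-negative scalar (possibly `Inf` for the standard variant).
#' @export
dunn_index <- function(points, labels = NULL,
                       variant = c("standard", "paper"),
                       metric = c("euclidean", "manhattan",
                                  "cosine", "jaccard")) {
  variant <- match.arg(variant)
  metric <- match.arg(metric)
  m <- point_matrix(points)
  if (is.null(labels) && is.data.frame(points)) labels <- points[["cluster"]]
  labels <- check_labels(labels, nrow(m))
  if (variant == "paper") {
    if (metric != "euclidean") {
      stop("the summation variant uses euclidean centroids", call. = FALSE)
    }
    return(davies_bouldin_like(m, labels))
  }
  d <- pairwise_distances(m, metric)
  ks <- sort(unique(labels))
  inter <- Inf
  diam <- 0
  for (i in seq_along(ks)) {
    in_i <- labels == ks[i]
    if (sum(in_i) > 1) diam <- max(diam, max(d[in_i, in_i]))
    for (j in seq_along(ks)) {
      if (j <= i) next
      inter <- min(inter, min(d[in_i, labels == ks[j]]))
    }
  }
  if (diam == 0) {
    warning("all intra-cluster diameters are zero; Dunn index is infinite",
            call. = FALSE)
    return(Inf)
  }
  inter / diam
}

davies_bouldin_like <- function(m, labels) {
  ks <- sort(unique(labels))
  cen <- cluster_centroids(m, labels)
  if (anyDuplicated(cen) > 0) {
    stop("coincident cluster centroids: index undefined", call. = FALSE)
  }
  radius <- vapply(seq_along(ks), function(i) {
    mem <- m[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((mem - matrix(cen[i, ], nrow(mem), ncol(m), byrow = TRUE))^2)))
  }, numeric(1))
  cen_d <- as.matrix(stats::dist(cen))
  k <- length(ks)
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (radius[i] + radius[j]) / cen_d[i, j], numeric(1)))
  }, numeric(1)))
}

#' Internal cluster-validity report
#'
#' Silhouette, Davies-Bouldin, and both Dunn variants for one labeled point
#' set, in a single row.
#'
#' @inheritParams silhouette_score
#' @return A one-row tibble: `silhouette`, `davies_bouldin`, `dunn_standard`,
#'   `dunn_paper`, `metric`, `n`, `k`.
#' @export
cluster_quality <- function(points, labels = NULL,
                            metric = c("euclidean", "manhattan",
                                       "cosine", "jaccard")) {
  metric <- match.arg(metric)
  m <- point_matrix(points)
  if (is.null(labels) && is.data.frame(points)) labels <- points[["cluster"]]
  labels <- check_labels(labels, nrow(m))
  tibble::tibble(
    silhouette = silhouette_score(m, labels, metric)$mean,
    davies_bouldin = davies_bouldin(m, labels),
    dunn_standard = dunn_index(m, labels, "standard", metric),
    dunn_paper = dunn_index(m, labels, "paper"),
    metric = metric,
    n = nrow(m),
    k = length(unique(labels))
  )
}
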