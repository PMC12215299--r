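test_that("point distances follow the standard definitions", {
  expect_equal(point_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(point_distance(c(0, 0), c(3, 4), "manhattan"), 7)
  expect_equal(point_distance(c(1, 1, 0), c(1, 0, 1), "jaccard"), 2 / 3)
  expect_equal(point_distance(c(1, 0), c(0, 1), "cosine"), 1)
  for (metric in c("euclidean", "manhattan", "cosine", "jaccard")) {
    x <- c(2, 3, 0.5)
    expect_equal(point_distance(x, x, metric), 0)
  }
  expect_error(point_distance(c(0, 0), c(0, 0), "cosine"), "undefined")
  expect_error(point_distance(1, c(1, 2)), "length")
})

test_that("pairwise distances agree with the scalar function", {
  m <- withr::with_seed(1, matrix(rnorm(8 * 3), 8, 3))
  m[2, ] <- 0  # exercise zero-vector handling under jaccard
  for (metric in c("euclidean", "manhattan", "cosine", "jaccard")) {
    d <- pairwise_distances(m, metric)
    for (i in 1:8) for (j in 1:8) {
      if (metric == "cosine" && (i == 2 || j == 2)) next
      expect_equal(d[i, j], oracle_dist(m[i, ], m[j, ], metric),
                   tolerance = 1e-12)
    }
  }
})

test_that("standardization centers and scales by the population sd", {
  out <- standardize_points(data.frame(a = c(1, 3)))
  expect_equal(out$a, c(-1, 1))
  again <- standardize_points(out)
  expect_equal(as.matrix(again), as.matrix(out), tolerance = 1e-12)
  m <- withr::with_seed(2, as.data.frame(matrix(rnorm(200), 50, 4)))
  z <- standardize_points(m)
  expect_true(all(abs(colMeans(as.matrix(z))) < 1e-12))
  expect_true(all(abs(apply(as.matrix(z), 2, function(v) mean(v^2)) - 1) < 1e-12))
  expect_error(standardize_points(data.frame(a = c(1, 2), b = 5)), "'b'")
})

test_that("k-means matches exhaustive enumeration on the 1-D fixture", {
  x <- c(0, 0.1, 10, 10.1)
  fit <- kmeans_cluster(data.frame(x = x), 2, seed = 1)
  best <- oracle_best_2partition(x)
  expect_equal(fit$inertia, best$inertia, tolerance = 1e-12)
  expect_equal(fit$inertia, 0.01)
  same <- fit$labels[1] == fit$labels[2] && fit$labels[3] == fit$labels[4] &&
    fit$labels[1] != fit$labels[3]
  expect_true(same)
})

test_that("inertia is non-increasing along every recorded trace", {
  for (seed in 1:10) {
    pts <- withr::with_seed(seed, matrix(rnorm(60 * 2), 60, 2))
    fit <- kmeans_cluster(pts, 4, seed = seed)
    expect_true(all(diff(fit$trace) <= 1e-9))
  }
})

test_that("k = n gives zero inertia and k bounds are enforced", {
  pts <- data.frame(x = c(1, 2, 3), y = c(0, 5, 1))
  fit <- kmeans_cluster(pts, 3, seed = 2)
  expect_equal(fit$inertia, 0)
  expect_error(kmeans_cluster(pts, 1, seed = 1), "k")
  expect_error(kmeans_cluster(pts, 4, seed = 1), "k")
})

test_that("k-means matches stats::kmeans inertia on an easy problem", {
  pts <- generate_labeled_points(3, 30, rbind(c(0, 0), c(12, 0), c(0, 12)),
                                 spread = 1, seed = 3)
  m <- point_matrix(pts)
  fit <- kmeans_cluster(m, 3, seed = 4, nstart = 5)
  ref <- withr::with_seed(5, stats::kmeans(m, 3, nstart = 10))
  expect_equal(fit$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("elbow curve drops hardest entering the true cluster count", {
  pts <- generate_labeled_points(3, 25, rbind(c(0, 0), c(25, 0), c(0, 25)),
                                 spread = 1, seed = 8)
  ec <- elbow_curve(pts, 2:6, seed = 9)
  drops <- -diff(ec$inertia)
  expect_equal(which.max(drops), 1L)  # the k=2 -> k=3 transition
  expect_true(all(diff(ec$inertia) <= 1e-9))
})

test_that("elbow inertia is non-increasing in k on random data", {
  for (seed in 1:5) {
    pts <- withr::with_seed(seed, matrix(rnorm(40 * 2), 40, 2))
    ec <- elbow_curve(pts, 2:8, seed = seed)
    expect_true(all(diff(ec$inertia) <= 1e-9))
  }
  ec1 <- elbow_curve(matrix(rnorm(10), 5, 2), 5, seed = 1)
  expect_equal(ec1$inertia, 0)
})

test_that("single linkage on {0, 1, 10} merges as hand-computed", {
  d <- agglomerative_cluster(data.frame(x = c(0, 1, 10)), "single")
  expect_equal(d$merges$height, c(1, 9))
  expect_identical(sort(c(d$merges$a[1], d$merges$b[1])), c(-2L, -1L))
  two <- agglomerative_cluster(data.frame(x = c(3, 7)), "complete")
  expect_equal(two$merges$height, 4)
  expect_error(agglomerative_cluster(data.frame(x = c(1, 2)), "ward", "manhattan"),
               "euclidean")
})

test_that("merge heights match the naive recompute-from-members oracle", {
  for (seed in 1:6) {
    m <- withr::with_seed(seed, matrix(rnorm(8 * 2), 8, 2))
    for (linkage in c("single", "complete", "average", "ward")) {
      d <- agglomerative_cluster(m, linkage)
      expect_equal(d$merges$height,
                   oracle_agglomerative_heights(m, linkage),
                   tolerance = 1e-9,
                   label = paste(linkage, "seed", seed))
      expect_true(all(diff(d$merges$height) >= -1e-9))
    }
  }
})

test_that("cutting the dendrogram recovers well-separated clusters", {
  pts <- generate_labeled_points(3, 15, rbind(c(0, 0), c(40, 0), c(0, 40)),
                                 spread = 1, seed = 10)
  d <- agglomerative_cluster(pts, "average")
  labels <- cut_clusters(d, 3)
  tab <- table(pts$cluster, labels)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0) == 1)))
})

test_that("silhouette matches the printed formula on the 1-D fixture", {
  pts <- data.frame(x = c(0, 0.1, 10, 10.1))
  s <- silhouette_score(pts, c(1, 1, 2, 2))
  expect_equal(s$widths$width[1], (10.05 - 0.1) / 10.05, tolerance = 1e-9)
  expect_true(all(s$widths$width >= -1 & s$widths$width <= 1))
})

test_that("coincident clusters give zero silhouette; singletons get zero", {
  pts <- data.frame(x = c(0, 0, 0, 0), y = c(1, 1, 1, 1))
  s <- silhouette_score(pts, c(1, 1, 2, 2))
  expect_equal(s$mean, 0)
  s2 <- silhouette_score(data.frame(x = c(0, 5, 6)), c(1, 2, 2))
  expect_equal(s2$widths$width[1], 0)  # singleton cluster
  expect_error(silhouette_score(pts, c(1, 1, 1, 1)), "2 clusters")
})

test_that("davies-bouldin matches the two-square hand computation", {
  sq <- data.frame(x = c(0, 0, 10, 10), y = c(0, 2, 0, 2))
  expect_equal(davies_bouldin(sq, c(1, 1, 2, 2)), 0.2, tolerance = 1e-9)
  # two singleton clusters have zero radii
  expect_equal(davies_bouldin(data.frame(x = c(0, 4)), c(1, 2)), 0)
  expect_error(
    davies_bouldin(data.frame(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0)),
                   c(1, 1, 2, 2)),
    "coincident")
})

test_that("shrinking within-cluster spread strictly decreases davies-bouldin", {
  base <- data.frame(x = c(-1, 1, 9, 11), y = c(0, 0, 0, 0))
  labels <- c(1, 1, 2, 2)
  prev <- Inf
  for (scale in c(1, 0.5, 0.25, 0.1)) {
    shrunk <- base
    shrunk$x <- c(-scale, scale, 10 - scale, 10 + scale)
    val <- davies_bouldin(shrunk, labels)
    expect_lt(val, prev)
    prev <- val
  }
})

test_that("dunn index matches hand computations in both variants", {
  sq <- data.frame(x = c(0, 0, 10, 10), y = c(0, 2, 0, 2))
  expect_equal(dunn_index(sq, c(1, 1, 2, 2), "standard"), 5, tolerance = 1e-9)
  expect_equal(dunn_index(sq, c(1, 1, 2, 2), "paper"), 0.2, tolerance = 1e-9)
  farther <- data.frame(x = c(0, 0, 20, 20), y = c(0, 2, 0, 2))
  expect_gt(dunn_index(farther, c(1, 1, 2, 2)), dunn_index(sq, c(1, 1, 2, 2)))
  expect_warning(val <- dunn_index(data.frame(x = c(0, 4)), c(1, 2)), "infinite")
  expect_identical(val, Inf)
})

test_that("validity indices match naive oracles on random labeled sets", {
  for (seed in 1:15) {
    rl <- random_labeled_points(seed)
    s <- silhouette_score(rl$m, rl$labels)
    o <- oracle_silhouette(rl$m, rl$labels)
    expect_equal(s$mean, o$mean, tolerance = 1e-10)
    expect_equal(s$widths$width, o$widths, tolerance = 1e-10)
    expect_equal(davies_bouldin(rl$m, rl$labels), oracle_dbi(rl$m, rl$labels),
                 tolerance = 1e-10)
    expect_equal(dunn_index(rl$m, rl$labels, "standard"),
                 oracle_dunn_standard(rl$m, rl$labels), tolerance = 1e-10)
    expect_equal(dunn_index(rl$m, rl$labels, "paper"), oracle_dbi(rl$m, rl$labels),
                 tolerance = 1e-10)
  }
})

test_that("indices are invariant to point order and label permutation", {
  rl <- random_labeled_points(99)
  q1 <- cluster_quality(rl$m, rl$labels)
  perm <- withr::with_seed(1, sample(nrow(rl$m)))
  q2 <- cluster_quality(rl$m[perm, ], rl$labels[perm])
  relabel <- max(rl$labels) + 1 - rl$labels
  q3 <- cluster_quality(rl$m, relabel)
  for (col in c("silhouette", "davies_bouldin", "dunn_standard", "dunn_paper")) {
    expect_equal(q1[[col]], q2[[col]], tolerance = 1e-10)
    expect_equal(q1[[col]], q3[[col]], tolerance = 1e-10)
  }
})

test_that("well-separated limit: silhouette -> 1, DBI -> 0, Dunn grows", {
  prev_dunn <- 0
  for (gap in c(10, 100, 1000)) {
    pts <- generate_labeled_points(2, 10, rbind(c(0, 0), c(gap, 0)),
                                   spread = 0.5, seed = 11)
    q <- cluster_quality(pts)
    if (gap == 1000) {
      expect_gt(q$silhouette, 0.99)
      expect_lt(q$davies_bouldin, 0.01)
    }
    expect_gt(q$dunn_standard, prev_dunn)
    prev_dunn <- q$dunn_standard
  }
})
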