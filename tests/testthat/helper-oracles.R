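# Naive reference implementations, deliberately written on different
# algorithmic routes than the package (per-pixel flood fill with an explicit
# stack, exhaustive searches, double/triple loops over the index definitions).

oracle_neighbors <- function(connectivity) {
  if (connectivity == 4) {
    list(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  } else {
    list(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  }
}

# connected-component labeling by stack-based flood fill, raster-order labels
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  nb <- oracle_neighbors(connectivity)
  lab <- matrix(0L, H, W)
  next_label <- 0L
  # first-pixel order: down each column, columns left to right (column-major)
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    next_label <- next_label + 1L
    stack_r <- integer(H * W); stack_c <- integer(H * W)
    stack_r[1] <- r0; stack_c[1] <- c0; top <- 1L
    lab[r0, c0] <- next_label
    while (top > 0L) {
      r <- stack_r[top]; c <- stack_c[top]; top <- top - 1L
      for (k in seq_along(nb$dr)) {
        rr <- r + nb$dr[k]; cc <- c + nb$dc[k]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- next_label
          top <- top + 1L
          stack_r[top] <- rr; stack_c[top] <- cc
        }
      }
    }
  }
  lab
}

oracle_area_open <- function(mask, min_area, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  if (max(lab) == 0) return(mask)
  sizes <- table(factor(lab[lab > 0], levels = seq_len(max(lab))))
  keep <- as.integer(names(sizes)[sizes >= min_area])
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# hole filling: flood the background from the border (complementary
# connectivity); anything not reached and not foreground is a hole
oracle_fill_holes <- function(mask, fg_connectivity = 8) {
  bg_conn <- if (fg_connectivity == 8) 4 else 8
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(FALSE, H + 2, W + 2)
  padded[2:(H + 1), 2:(W + 1)] <- mask
  bg_lab <- oracle_label(!padded, bg_conn)
  outside <- bg_lab == bg_lab[1, 1]
  filled <- padded | !outside
  filled[2:(H + 1), 2:(W + 1)]
}

oracle_otsu <- function(histogram) {
  best_t <- NA_integer_; best_v <- -Inf
  intens <- 0:255
  for (t in 1:255) {  # threshold T: class0 = {i < T}, class1 = {i >= T}
    w0 <- sum(histogram[intens < t]); w1 <- sum(histogram[intens >= t])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(histogram[intens < t] * intens[intens < t]) / w0
    mu1 <- sum(histogram[intens >= t] * intens[intens >= t]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-9) { best_v <- v; best_t <- t }
  }
  best_t
}

oracle_dist <- function(x, y, metric = "euclidean") {
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    cosine = 1 - sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2))),
    jaccard = {
      bx <- x != 0; by <- y != 0
      if (!any(bx | by)) 0 else 1 - sum(bx & by) / sum(bx | by)
    })
}

oracle_silhouette <- function(m, labels, metric = "euclidean") {
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(vapply(same, function(j) oracle_dist(m[i, ], m[j, ], metric),
                     numeric(1)))
    b <- Inf
    for (kk in setdiff(unique(labels), labels[i])) {
      oth <- which(labels == kk)
      b <- min(b, mean(vapply(oth, function(j) oracle_dist(m[i, ], m[j, ], metric),
                              numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  list(widths = s, mean = mean(s))
}

oracle_dbi <- function(m, labels) {
  ks <- sort(unique(labels))
  k <- length(ks)
  cen <- lapply(ks, function(kk) colMeans(m[labels == kk, , drop = FALSE]))
  rad <- vapply(seq_len(k), function(i) {
    mem <- m[labels == ks[i], , drop = FALSE]
    mean(apply(mem, 1, function(p) sqrt(sum((p - cen[[i]])^2))))
  }, numeric(1))
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      worst <- max(worst, (rad[i] + rad[j]) / sqrt(sum((cen[[i]] - cen[[j]])^2)))
    }
    total <- total + worst
  }
  total / k
}

oracle_dunn_standard <- function(m, labels, metric = "euclidean") {
  ks <- sort(unique(labels))
  inter <- Inf; diam <- 0
  for (i in seq_along(ks)) for (j in seq_along(ks)) {
    a_idx <- which(labels == ks[i]); b_idx <- which(labels == ks[j])
    if (i == j) {
      for (p in a_idx) for (q in a_idx) {
        diam <- max(diam, oracle_dist(m[p, ], m[q, ], metric))
      }
    } else {
      for (p in a_idx) for (q in b_idx) {
        inter <- min(inter, oracle_dist(m[p, ], m[q, ], metric))
      }
    }
  }
  if (diam == 0) Inf else inter / diam
}

# naive agglomerative clustering: recompute every cluster-pair distance from
# the member points at every step (no Lance-Williams update)
oracle_agglomerative_heights <- function(m, linkage, metric = "euclidean") {
  clusters <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    if (linkage == "ward") {
      ca <- colMeans(m[a, , drop = FALSE]); cb <- colMeans(m[b, , drop = FALSE])
      na <- length(a); nb <- length(b)
      sqrt(2 * na * nb / (na + nb)) * sqrt(sum((ca - cb)^2))
    } else {
      ds <- c()
      for (p in a) for (q in b) ds <- c(ds, oracle_dist(m[p, ], m[q, ], metric))
      switch(linkage, single = min(ds), complete = max(ds), average = mean(ds))
    }
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- cluster_dist(clusters[[i]], clusters[[j]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# every partition of points into 2 nonempty clusters, with centroid cost
oracle_best_2partition <- function(x) {
  n <- length(x)
  best_inertia <- Inf; best_assign <- NULL
  for (code in 1:(2^(n - 1) - 1)) {   # fix point 1 in cluster 1
    assign <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    inertia <- 0
    for (g in 1:2) {
      mem <- x[assign == g]
      inertia <- inertia + sum((mem - mean(mem))^2)
    }
    if (inertia < best_inertia) { best_inertia <- inertia; best_assign <- assign }
  }
  list(inertia = best_inertia, assign = best_assign)
}

oracle_classification <- function(y_true, y_pred, averaging = "macro") {
  classes <- sort(unique(y_true))
  per <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    jac <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
    c(prec = prec, rec = rec, f1 = f1, jac = jac,
      support = sum(y_true == cl), tp = tp, fp = fp, fn = fn)
  })
  per <- do.call(rbind, per)
  w <- switch(averaging,
    macro = rep(1 / nrow(per), nrow(per)),
    weighted = per[, "support"] / sum(per[, "support"])
  )
  n <- length(y_true)
  if (averaging == "micro") {
    tp <- sum(per[, "tp"]); fp <- sum(per[, "fp"]); fn <- sum(per[, "fn"])
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    out <- c(precision = prec, recall = rec,
             f1 = 2 * prec * rec / (prec + rec),
             jaccard = tp / (tp + fp + fn))
  } else {
    out <- c(precision = sum(w * per[, "prec"]), recall = sum(w * per[, "rec"]),
             f1 = sum(w * per[, "f1"]), jaccard = sum(w * per[, "jac"]))
  }
  # MCC via covariance form over one-hot encodings
  t_oh <- outer(y_true, classes, `==`) * 1
  p_oh <- outer(y_pred, classes, `==`) * 1
  cov_tp <- sum(diag(stats::cov(t_oh, p_oh)))
  cov_tt <- sum(diag(stats::cov(t_oh, t_oh)))
  cov_pp <- sum(diag(stats::cov(p_oh, p_oh)))
  mcc <- if (cov_tt == 0 || cov_pp == 0) 0 else cov_tp / sqrt(cov_tt * cov_pp)
  c(out, hamming_loss = mean(y_true != y_pred), mcc = mcc)
}

oracle_regression <- function(y, p) {
  n <- length(y)
  c(mae = sum(abs(y - p)) / n,
    mse = sum((y - p)^2) / n,
    rmse = sqrt(sum((y - p)^2) / n),
    r2 = 1 - sum((p - y)^2) / sum((y - mean(y))^2),
    rmsle = sqrt(sum((log(1 + p) - log(1 + y))^2) / n),
    smape = 100 / n * sum(ifelse(abs(p) + abs(y) == 0, 0,
                                 2 * abs(p - y) / (abs(p) + abs(y)))))
}

# seeded blobby-or-speckled random binary mask
random_mask <- function(seed, H = 64, W = 64) {
  withr::with_seed(seed, {
    p <- stats::runif(1, 0.2, 0.6)
    matrix(stats::runif(H * W) < p, H, W)
  })
}

random_labeled_points <- function(seed, n_max = 50, d_max = 4, k_max = 5) {
  withr::with_seed(seed, {
    k <- sample(2:k_max, 1)
    n <- sample(max(k + 1, 10):n_max, 1)
    d <- sample(2:d_max, 1)
    m <- matrix(stats::rnorm(n * d), n, d)
    labels <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    list(m = m, labels = labels)
  })
}
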