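#' Specification for a synthetic plantar pressure image
#'
#' Describes a pressure-map-like RGB image: red-dominant disks (pressure
#' blobs) on a non-red background, each blob assigned to the forefoot or the
#' hindfoot. Blobs are rendered with the peak red intensity at the center,
#' decaying linearly to `rim_intensity` at the rim; green and blue inside
#' blobs are held at `blob_gb`, far enough below red that the default red
#' dominance margin always passes.
#'
#' @param height,width Image size in pixels.
#' @param blobs A data frame with one row per blob and columns `row`, `col`
#'   (center, pixels), `radius` (pixels), `peak` (center red intensity) and
#'   `region` (`"forefoot"` or `"hindfoot"`).
#' @param background RGB triple with `red - max(green, blue) < 0`.
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise added
#'   after the ground truth is computed (`0` = noise free).
#' @param seed Integer seed driving all randomness.
#' @param rim_intensity Red value at the blob rim.
#' @param blob_gb Green/blue value inside blobs.
#' @return A validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(height = 120, width = 80, blobs,
                           background = c(0, 0, 120),
                           noise_sd = 0, seed = 1L,
                           rim_intensity = 140, blob_gb = 20) {
  blobs <- tibble::as_tibble(blobs)
  needed <- c("row", "col", "radius", "peak", "region")
  if (!all(needed %in% names(blobs)) || nrow(blobs) == 0L) {
    stop("`blobs` needs columns row, col, radius, peak, region", call. = FALSE)
  }
  stopifnot(
    height >= 1, width >= 1, noise_sd >= 0,
    all(blobs$region %in% c("forefoot", "hindfoot")),
    all(blobs$radius >= 1),
    all(blobs$peak > 30 & blobs$peak <= 255),
    all(blobs$peak >= rim_intensity),
    background[1] - max(background[2:3]) < 0
  )
  if (any(blobs$row - blobs$radius < 1 | blobs$row + blobs$radius > height |
          blobs$col - blobs$radius < 1 | blobs$col + blobs$radius > width)) {
    stop("every blob must fit inside the image", call. = FALSE)
  }
  ff <- blobs$row[blobs$region == "forefoot"]
  hf <- blobs$row[blobs$region == "hindfoot"]
  if (length(ff) > 0 && length(hf) > 0 && max(ff) >= min(hf)) {
    stop("forefoot blob centers must lie strictly above hindfoot blob centers",
         call. = FALSE)
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         blobs = blobs, background = as.integer(background),
         noise_sd = noise_sd, seed = as.integer(seed),
         rim_intensity = as.integer(rim_intensity),
         blob_gb = as.integer(blob_gb)),
    class = "synthetic_spec"
  )
}

blob_pixels <- function(spec, i) {
  b <- spec$blobs[i, ]
  rr <- max(1L, floor(b$row - b$radius)):min(spec$height, ceiling(b$row + b$radius))
  cc <- max(1L, floor(b$col - b$radius)):min(spec$width, ceiling(b$col + b$radius))
  g <- expand.grid(row = rr, col = cc)
  d <- sqrt((g$row - b$row)^2 + (g$col - b$col)^2)
  inside <- d <= b$radius
  val <- round(spec$rim_intensity +
                 (b$peak - spec$rim_intensity) * (1 - d[inside] / b$radius))
  list(row = g$row[inside], col = g$col[inside], red = as.integer(val))
}

#' Generate a synthetic pressure image with its ground truth
#'
#' Renders the spec noise free, computes the ground-truth manifest (pressure
#' pixel set, per-region red-intensity sums, true ratio, true foot type, and
#' per-blob areas) from that rendering, then adds seeded Gaussian noise
#' (clipped to `[0, 255]`). Identical spec and seed give identical images.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `image` (a [pressure_image()]) and `truth`, a list with
#'   `mask` (logical ground-truth pixel set), `forefoot_pressure`,
#'   `hindfoot_pressure`, `ratio`, `foot_type`, `blob_areas`, and the seed.
#' @export
generate_pressure_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$height; W <- spec$width
  red <- matrix(spec$background[1], H, W)
  grn <- matrix(spec$background[2], H, W)
  blu <- matrix(spec$background[3], H, W)
  region_of <- matrix(NA_character_, H, W)
  blob_areas <- integer(nrow(spec$blobs))
  for (i in seq_len(nrow(spec$blobs))) {
    px <- blob_pixels(spec, i)
    blob_areas[i] <- length(px$row)
    idx <- cbind(px$row, px$col)
    other <- region_of[idx]
    clash <- !is.na(other) & other != spec$blobs$region[i]
    if (any(clash)) {
      stop("blobs from different regions overlap across the midline",
           call. = FALSE)
    }
    red[idx] <- pmax(red[idx], px$red)
    grn[idx] <- spec$blob_gb
    blu[idx] <- spec$blob_gb
    region_of[idx] <- spec$blobs$region[i]
  }
  mask <- !is.na(region_of)
  ff <- sum(as.numeric(red[!is.na(region_of) & region_of == "forefoot"]))
  hf <- sum(as.numeric(red[!is.na(region_of) & region_of == "hindfoot"]))
  cls <- classify_foot_type(ff, hf)
  truth <- list(
    mask = mask,
    forefoot_pressure = ff, hindfoot_pressure = hf,
    ratio = cls$ratio, foot_type = cls$foot_type,
    blob_areas = blob_areas, seed = spec$seed
  )
  px <- array(c(red, grn, blu), dim = c(H, W, 3))
  if (spec$noise_sd > 0) {
    px <- withr::with_seed(spec$seed, {
      px + stats::rnorm(length(px), sd = spec$noise_sd)
    })
    px <- pmin(pmax(round(px), 0), 255)
  }
  list(image = pressure_image(px), truth = truth)
}

#' Two-region foot layout aimed at a target pressure ratio
#'
#' Builds a [synthetic_spec()] with two forefoot disks and one hindfoot disk
#' laid out so the bounding-box midpoint split falls in the gap between the
#' regions, and solves the forefoot peak intensity so the rendered
#' ground-truth ratio lands on `target_ratio` (up to per-pixel rounding,
#' well under 1% relative).
#'
#' @param target_ratio Desired forefoot/hindfoot pressure ratio (roughly in
#'   `[0.25, 2.6]` for the default geometry).
#' @param seed Seed recorded in the spec.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @return A [synthetic_spec()].
#' @export
synthetic_foot_spec <- function(target_ratio, seed = 1L, noise_sd = 0) {
  stopifnot(target_ratio > 0)
  H <- 120L; W <- 80L; rim <- 140L; p_max <- 245
  r_h <- 16
  disk_weights <- function(r) {
    g <- expand.grid(dr = -r:r, dc = -r:r)
    d <- sqrt(g$dr^2 + g$dc^2)
    inside <- d <= r
    c(n = sum(inside), w = sum(1 - d[inside] / r))
  }
  dh <- disk_weights(r_h)
  # rendered sum is affine in the peak: S(p) = rim * n + (p - rim) * w;
  # pick the forefoot radius, then solve the two peaks jointly so both stay
  # in [rim, p_max] while the sum ratio hits the target
  sum_range <- function(n, w) c(rim * n, rim * n + (p_max - rim) * w)
  sh_rng <- sum_range(dh["n"], dh["w"])
  best <- NULL
  for (r in 4:18) {
    df <- disk_weights(r)
    sf_rng <- 2 * sum_range(df["n"], df["w"])   # two forefoot disks
    # feasible iff the target line crosses the rectangle of achievable sums
    lo <- max(sf_rng[1] / target_ratio, sh_rng[1])
    hi <- min(sf_rng[2] / target_ratio, sh_rng[2])
    if (lo > hi) next
    s_h <- min(max((sh_rng[1] + sh_rng[2]) / 2, lo), hi)
    p_h <- rim + (s_h - rim * dh["n"]) / dh["w"]
    p_f <- rim + (target_ratio * s_h / 2 - rim * df["n"]) / df["w"]
    score <- abs(p_f - 195) + abs(p_h - 195) / 10
    if (is.null(best) || score < best$score) {
      best <- list(r = r, p_f = unname(p_f), p_h = unname(p_h), score = score)
    }
  }
  if (is.null(best)) {
    stop("target_ratio ", target_ratio, " is outside the range this layout can render",
         call. = FALSE)
  }
  synthetic_spec(
    H, W,
    tibble::tibble(row = c(28, 28, 90), col = c(21, 59, 40),
                   radius = c(best$r, best$r, r_h),
                   peak = c(best$p_f, best$p_f, best$p_h),
                   region = c("forefoot", "forefoot", "hindfoot")),
    noise_sd = noise_sd, seed = seed
  )
}

#' Generate labeled Gaussian point clouds
#'
#' Seeded isotropic Gaussian draws around each center; fixtures for the
#' clustering and validity-index functions.
#'
#' @param n_clusters Number of clusters (`>= 2`).
#' @param points_per_cluster Points drawn around each center (scalar or one
#'   value per cluster).
#' @param centers A `n_clusters` x d matrix (or data frame) of pairwise
#'   distinct centers.
#' @param spread Isotropic standard deviation (`> 0`).
#' @param seed Integer seed.
#' @return A tibble with coordinate columns `x1..xd` and an integer `cluster`
#'   column in `1..n_clusters`.
#' @export
generate_labeled_points <- function(n_clusters, points_per_cluster, centers,
                                    spread, seed = 1L) {
  if (n_clusters < 2) {
    stop("validity indices need at least 2 clusters", call. = FALSE)
  }
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == n_clusters, spread > 0)
  if (anyDuplicated(centers) > 0) {
    stop("cluster centers must be pairwise distinct", call. = FALSE)
  }
  npc <- rep_len(as.integer(points_per_cluster), n_clusters)
  d <- ncol(centers)
  pts <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_len(n_clusters), function(i) {
      matrix(stats::rnorm(npc[i] * d, sd = spread), ncol = d) +
        matrix(centers[i, ], npc[i], d, byrow = TRUE)
    }))
  })
  out <- tibble::as_tibble(as.data.frame(pts), .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(d))
  out$cluster <- rep(seq_len(n_clusters), npc)
  out
}

#' Drop the label column from a labeled point tibble
#'
#' @param points A data frame; the `cluster` column (if present) is removed.
#' @return A numeric matrix of coordinates.
#' @export
point_matrix <- function(points) {
  df <- as.data.frame(points)
  df$cluster <- NULL
  as.matrix(df)
}
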