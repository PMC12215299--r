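#' Segmentation parameters
#'
#' Bundles every tunable of the pressure-segmentation pipeline. The pipeline
#' order is fixed: redness thresholding, area opening, morphological closing,
#' hole filling.
#'
#' @param threshold_mode `"otsu"` (threshold chosen on the red-band histogram
#'   by between-class variance maximization) or `"fixed"`.
#' @param fixed_threshold Red intensity in `[0, 255]`; required when
#'   `threshold_mode = "fixed"`.
#' @param red_dominance_margin Minimum excess of red over `max(green, blue)`
#'   for a pixel to count as red; excludes orange/yellow colormap zones.
#' @param min_blob_area Connected components smaller than this many pixels are
#'   removed as noise.
#' @param closing_radius Radius (pixels) of the disk structuring element used
#'   for border-smoothing morphological closing; `0` disables closing.
#' @param connectivity Pixel connectivity for components: `8` (diagonal contact
#'   joins blobs, the usual blob-analysis convention) or `4`.
#' @return A `segmentation_params` object (a validated named list).
#' @export
segmentation_params <- function(threshold_mode = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                red_dominance_margin = 30,
                                min_blob_area = 20,
                                closing_radius = 2,
                                connectivity = 8) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed") {
    if (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 255) {
      stop("`fixed_threshold` in [0, 255] is required when threshold_mode = \"fixed\"",
           call. = FALSE)
    }
  }
  stopifnot(
    red_dominance_margin >= 0,
    min_blob_area >= 1,
    closing_radius >= 0,
    connectivity %in% c(4L, 8L)
  )
  structure(
    list(
      threshold_mode = threshold_mode,
      fixed_threshold = if (!is.null(fixed_threshold)) as.integer(fixed_threshold),
      red_dominance_margin = as.integer(red_dominance_margin),
      min_blob_area = as.integer(min_blob_area),
      closing_radius = as.integer(closing_radius),
      connectivity = as.integer(connectivity)
    ),
    class = "segmentation_params"
  )
}

#' Otsu threshold from a 256-bin intensity histogram
#'
#' Returns the intensity `T` in `[0, 255]` such that marking pixels with
#' intensity `>= T` maximizes between-class variance of the two classes the
#' cut induces. Ties are broken toward the lower intensity.
#'
#' @param histogram Integer vector of 256 bin counts (bin `i + 1` counts
#'   intensity `i`).
#' @return The threshold intensity, an integer in `[1, 255]`.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0)) {
    stop("`histogram` must be 256 non-negative bin counts", call. = FALSE)
  }
  if (sum(histogram > 0) < 2L) {
    stop("degenerate histogram: red band takes a single value; ",
         "use threshold_mode = \"fixed\" with an explicit threshold",
         call. = FALSE)
  }
  counts <- as.numeric(histogram)
  intens <- 0:255
  total <- sum(counts)
  # cut t puts intensities <= t in class 0; candidate cuts 0..254
  w0 <- cumsum(counts)[1:255]
  m0 <- cumsum(counts * intens)[1:255]
  w1 <- total - w0
  mu_total <- sum(counts * intens)
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  mu0 <- m0[valid] / w0[valid]
  mu1 <- (mu_total - m0[valid]) / w1[valid]
  sigma_b[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  cut <- which.max(sigma_b) - 1L   # which.max takes the first (lowest) maximum
  cut + 1L
}

#' Binary pressure mask from red dominance
#'
#' Marks a pixel as pressure iff `red >= T` and
#' `red - max(green, blue) >= red_dominance_margin`, where `T` is the fixed
#' threshold or the Otsu threshold of the red-band histogram. This is the raw
#' mask, before morphological enhancement; see [segment_pressure()] for the
#' full pipeline.
#'
#' @param image A [pressure_image()].
#' @param params A [segmentation_params()].
#' @return A `pressure_mask`: a logical H x W matrix carrying `params` as an
#'   attribute.
#' @export
redness_mask <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "pressure_image"), inherits(params, "segmentation_params"))
  red <- image[, , 1]
  if (params$threshold_mode == "otsu") {
    hist256 <- tabulate(as.vector(red) + 1L, nbins = 256L)
    thr <- otsu_threshold(hist256)
  } else {
    thr <- params$fixed_threshold
  }
  grid <- red >= thr & (red - pmax(image[, , 2], image[, , 3])) >= params$red_dominance_margin
  new_pressure_mask(grid, params, threshold = thr)
}

new_pressure_mask <- function(grid, params, threshold = NULL) {
  structure(grid, params = params, threshold = threshold, class = "pressure_mask")
}

#' @export
print.pressure_mask <- function(x, ...) {
  cat(sprintf("<pressure_mask> %d x %d px, %d marked\n", nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# ---- binary morphology primitives ------------------------------------------

# offsets (dr, dc) of a disk structuring element of the given radius
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE])
}

# OR of the mask shifted by every offset: binary dilation (FALSE outside)
shift_any <- function(m, offsets) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    rows <- max(1L, 1L + dr):min(H, H + dr)
    cols <- max(1L, 1L + dc):min(W, W + dc)
    out[rows, cols] <- out[rows, cols] | m[rows - dr, cols - dc]
  }
  out
}

binary_dilate <- function(m, radius) {
  if (radius < 1) return(m)
  shift_any(m, disk_offsets(radius))
}

binary_erode <- function(m, radius) {
  if (radius < 1) return(m)
  !shift_any(!m, disk_offsets(radius))
}

# closing on a canvas padded by the SE radius, so border pixels are never
# eroded away and closing stays extensive (output is a superset of the input)
binary_close <- function(m, radius) {
  if (radius < 1) return(m)
  r <- as.integer(radius)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L * r, W + 2L * r)
  pad[(r + 1L):(r + H), (r + 1L):(r + W)] <- m
  closed <- binary_erode(binary_dilate(pad, r), r)
  closed[(r + 1L):(r + H), (r + 1L):(r + W)]
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(dr = rep(-1:1, times = 3)[-5], dc = rep(-1:1, each = 3)[-5])
  }
}

#' Label connected components of a binary mask
#'
#' Labels are assigned in raster order (top-to-bottom, then left-to-right) of
#' each component's first pixel; `0` marks background. Implemented as
#' vectorized minimum-label propagation to a fixed point.
#'
#' @param mask A logical matrix (or `pressure_mask`).
#' @param connectivity `4` or `8`.
#' @return An integer matrix of the same shape; values `0, 1, ..., n_components`.
#' @export
label_components <- function(mask, connectivity = 8) {
  connectivity <- as.integer(connectivity)
  stopifnot(connectivity %in% c(4L, 8L))
  m <- unclass(mask)
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  lab[m] <- seq_len(sum(m))
  if (!any(m)) return(lab)
  offs <- neighbor_offsets(connectivity)
  big <- .Machine$integer.max
  work <- matrix(big, H, W)
  work[m] <- lab[m]
  repeat {
    nxt <- work
    for (k in seq_len(nrow(offs))) {
      dr <- offs[k, 1]; dc <- offs[k, 2]
      rows <- max(1L, 1L + dr):min(H, H + dr)
      cols <- max(1L, 1L + dc):min(W, W + dc)
      nxt[rows, cols] <- pmin(nxt[rows, cols], work[rows - dr, cols - dc])
    }
    nxt[!m] <- big  # background never carries labels
    if (identical(nxt, work)) break
    work <- nxt
  }
  out <- matrix(0L, H, W)
  roots <- work[m]
  # canonical labels: 1..k in raster order of each component's minimal pixel id
  out[m] <- match(roots, sort(unique(roots)))
  out
}

#' Remove connected components smaller than a minimum area
#'
#' Morphological area opening: every connected component with fewer than
#' `min_blob_area` pixels is deleted; larger components are untouched.
#'
#' @param mask A `pressure_mask` (or logical matrix).
#' @param min_blob_area Minimum component area in pixels (`>= 1`).
#' @param connectivity `4` or `8`; defaults to the mask's own parameters when
#'   present.
#' @return A mask of the same class and shape.
#' @export
area_opening <- function(mask, min_blob_area = NULL, connectivity = NULL) {
  p <- attr(mask, "params")
  if (is.null(min_blob_area)) min_blob_area <- p$min_blob_area
  if (is.null(connectivity)) connectivity <- if (is.null(p)) 8L else p$connectivity
  stopifnot(min_blob_area >= 1)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- lab > 0L & sizes[pmax(lab, 1L)] >= min_blob_area
  out <- mask
  out[] <- keep
  out
}

#' Smooth borders and fill holes in a pressure mask
#'
#' Morphological closing with a disk structuring element of the given radius,
#' followed by filling of every background region not connected to the image
#' border. The output pixel set is always a superset of the input. Background
#' connectivity is the complement of the foreground connectivity (8-connected
#' foreground implies 4-connected background), the usual digital-topology
#' convention.
#'
#' @inheritParams area_opening
#' @param closing_radius Disk radius in pixels; `0` skips closing but still
#'   fills holes.
#' @return A mask of the same class and shape.
#' @export
close_and_fill <- function(mask, closing_radius = NULL, connectivity = NULL) {
  p <- attr(mask, "params")
  if (is.null(closing_radius)) closing_radius <- p$closing_radius
  if (is.null(connectivity)) connectivity <- if (is.null(p)) 8L else p$connectivity
  stopifnot(closing_radius >= 0)
  m <- unclass(mask)
  closed <- binary_close(m, closing_radius)
  bg_conn <- if (connectivity == 8L) 4L else 8L
  bg <- label_components(!closed, bg_conn)
  H <- nrow(closed); W <- ncol(closed)
  border_labels <- unique(c(bg[1, ], bg[H, ], bg[, 1], bg[, W]))
  border_labels <- border_labels[border_labels > 0L]
  filled <- closed | (bg > 0L & !(bg %in% border_labels))
  out <- mask
  out[] <- filled
  out
}

#' Blob analysis: per-component statistics
#'
#' One row per connected component of the mask, ordered by the component
#' bounding box (`row_min`, then `col_min`). The red-intensity total is the
#' pressure proxy used downstream.
#'
#' @param mask A `pressure_mask` (or logical matrix) of the same size as
#'   `image`.
#' @param image The [pressure_image()] the mask was derived from.
#' @param connectivity `4` or `8`; defaults to the mask's parameters.
#' @return A tibble with columns `blob_id`, `area_px`, `centroid_row`,
#'   `centroid_col`, `mean_r`, `mean_g`, `mean_b`, `total_red_intensity`,
#'   `row_min`, `col_min`, `row_max`, `col_max`.
#' @export
find_blobs <- function(mask, image, connectivity = NULL) {
  stopifnot(inherits(image, "pressure_image"))
  if (!all(dim(mask) == dim(image)[1:2])) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  p <- attr(mask, "params")
  if (is.null(connectivity)) connectivity <- if (is.null(p)) 8L else p$connectivity
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(
      blob_id = integer(), area_px = integer(),
      centroid_row = double(), centroid_col = double(),
      mean_r = double(), mean_g = double(), mean_b = double(),
      total_red_intensity = double(),
      row_min = integer(), col_min = integer(),
      row_max = integer(), col_max = integer()
    ))
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  red <- image[, , 1][lab > 0L]
  grn <- image[, , 2][lab > 0L]
  blu <- image[, , 3][lab > 0L]
  tbl <- tibble::tibble(
    label = l, row = idx[, 1], col = idx[, 2],
    red = red, green = grn, blue = blu
  )
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$label),
    area_px = dplyr::n(),
    centroid_row = mean(.data$row),
    centroid_col = mean(.data$col),
    mean_r = mean(.data$red),
    mean_g = mean(.data$green),
    mean_b = mean(.data$blue),
    total_red_intensity = sum(as.numeric(.data$red)),
    row_min = min(.data$row), col_min = min(.data$col),
    row_max = max(.data$row), col_max = max(.data$col),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$row_min, .data$col_min)
  out$blob_id <- seq_len(nrow(out))
  dplyr::select(out, "blob_id", dplyr::everything(), -"label")
}

#' Full segmentation pipeline
#'
#' Threshold (red dominance), area opening, closing, hole filling — in that
#' order.
#'
#' @inheritParams redness_mask
#' @return The enhanced `pressure_mask`.
#' @export
segment_pressure <- function(image, params = segmentation_params()) {
  mask <- redness_mask(image, params)
  mask <- area_opening(mask)
  close_and_fill(mask)
}

#' Write a binary mask as a PNG
#'
#' @param mask A `pressure_mask` or logical matrix.
#' @param path Output `.png` path (marked pixels white).
#' @return `path`, invisibly.
#' @export
write_pressure_mask <- function(mask, path) {
  png::writePNG(unclass(mask) * 1, target = path)
  invisible(path)
}
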