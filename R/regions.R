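#' Split a pressure mask into forefoot and hindfoot
#'
#' The split row is the midpoint of the bounding box of all marked pixels:
#' `split_row = floor((row_min + row_max + 1) / 2)`. With toes at the top
#' (`toes_up`), marked pixels in rows strictly above `split_row` form the
#' forefoot and the rest the hindfoot; `toes_down` swaps the two. The split is
#' per pixel, so the two regions always partition the mask and region
#' pressures add up to the whole-mask pressure exactly.
#'
#' @param mask A nonempty `pressure_mask` (or logical matrix).
#' @param orientation `"toes_up"` (default) or `"toes_down"`.
#' @return A list with logical matrices `forefoot` and `hindfoot` and the
#'   integer `split_row`.
#' @export
split_regions <- function(mask, orientation = c("toes_up", "toes_down")) {
  orientation <- match.arg(orientation)
  m <- unclass(mask)
  if (!any(m)) stop("empty foot: mask has no marked pixels", call. = FALSE)
  rows <- which(rowSums(m) > 0)
  split_row <- (min(rows) + max(rows) + 1L) %/% 2L
  above <- m & (row(m) < split_row)
  below <- m & !above
  if (orientation == "toes_up") {
    list(forefoot = above, hindfoot = below, split_row = split_row)
  } else {
    list(forefoot = below, hindfoot = above, split_row = split_row)
  }
}

#' Summed red intensity over a pixel set
#'
#' The pressure proxy: the sum of red-band values over the pixels of a region.
#'
#' @param region A logical matrix the size of the image, or a two-column
#'   (row, col) matrix of pixel coordinates.
#' @param image A [pressure_image()].
#' @return The summed red intensity (a non-negative number; `0` for an empty
#'   set).
#' @export
region_pressure <- function(region, image) {
  stopifnot(inherits(image, "pressure_image"))
  red <- image[, , 1]
  if (is.logical(region)) {
    if (!all(dim(region) == dim(red))) {
      stop("region mask and image dimensions differ", call. = FALSE)
    }
    return(sum(as.numeric(red[region])))
  }
  region <- as.matrix(region)
  if (nrow(region) == 0L) return(0)
  if (min(region) < 1 || max(region[, 1]) > nrow(red) || max(region[, 2]) > ncol(red)) {
    stop("region coordinates fall outside the image", call. = FALSE)
  }
  sum(as.numeric(red[region]))
}

#' Classify foot type from the forefoot-hindfoot pressure ratio
#'
#' `ratio = forefoot / hindfoot`. Type 0 (hindfoot dominant) when
#' `ratio < 0.8`; Type 1 (balanced) when `0.8 <= ratio <= 1.2`; Type 2
#' (forefoot dominant) when `ratio > 1.2`. A zero hindfoot pressure with
#' positive forefoot pressure gives `ratio = Inf`, Type 2.
#'
#' @param forefoot_pressure,hindfoot_pressure Non-negative pressures
#'   (vectorized; recycled to a common length).
#' @return A tibble with columns `forefoot_pressure`, `hindfoot_pressure`,
#'   `ratio`, `foot_type` (integer 0/1/2).
#' @examples
#' classify_foot_type(c(500, 1000, 1500), 1000)
#' @export
classify_foot_type <- function(forefoot_pressure, hindfoot_pressure) {
  n <- max(length(forefoot_pressure), length(hindfoot_pressure))
  ff <- rep_len(as.numeric(forefoot_pressure), n)
  hf <- rep_len(as.numeric(hindfoot_pressure), n)
  if (any(ff < 0 | hf < 0)) stop("pressures must be non-negative", call. = FALSE)
  if (any(ff == 0 & hf == 0)) {
    stop("empty foot: both region pressures are zero", call. = FALSE)
  }
  ratio <- ifelse(hf == 0, Inf, ff / hf)
  foot_type <- ifelse(ratio < 0.8, 0L, ifelse(ratio <= 1.2, 1L, 2L))
  tibble::tibble(
    forefoot_pressure = ff, hindfoot_pressure = hf,
    ratio = ratio, foot_type = as.integer(foot_type)
  )
}

region_bbox <- function(m) {
  if (!any(m)) return(c(row_min = NA_integer_, col_min = NA_integer_,
                        row_max = NA_integer_, col_max = NA_integer_))
  idx <- which(m, arr.ind = TRUE)
  c(row_min = min(idx[, 1]), col_min = min(idx[, 2]),
    row_max = max(idx[, 1]), col_max = max(idx[, 2]))
}

#' Analyze a plantar pressure image end to end
#'
#' Runs the full pipeline — segmentation, blob analysis, forefoot/hindfoot
#' split, pressure quantification and foot-type classification — and returns a
#' region report.
#'
#' @param image A [pressure_image()].
#' @param params A [segmentation_params()].
#' @param orientation `"toes_up"` or `"toes_down"` (which end of the image the
#'   toes point to).
#' @return A `region_report`: a list with
#'   \describe{
#'     \item{report}{one-row tibble: `forefoot_pressure`, `hindfoot_pressure`,
#'       `ratio`, `foot_type`, `split_row` and the bounding boxes of both
#'       regions}
#'     \item{mask}{the enhanced `pressure_mask`}
#'     \item{blobs}{the [find_blobs()] tibble}
#'     \item{params, orientation}{the configuration used}
#'   }
#' @export
analyze_pressure_image <- function(image, params = segmentation_params(),
                                   orientation = c("toes_up", "toes_down")) {
  orientation <- match.arg(orientation)
  mask <- segment_pressure(image, params)
  if (!any(mask)) stop("empty foot: no pressure region detected", call. = FALSE)
  blobs <- find_blobs(mask, image)
  parts <- split_regions(mask, orientation)
  ff <- region_pressure(parts$forefoot, image)
  hf <- region_pressure(parts$hindfoot, image)
  cls <- classify_foot_type(ff, hf)
  fb <- region_bbox(parts$forefoot)
  hb <- region_bbox(parts$hindfoot)
  report <- tibble::tibble(
    forefoot_pressure = ff, hindfoot_pressure = hf,
    ratio = cls$ratio, foot_type = cls$foot_type,
    split_row = parts$split_row,
    forefoot_row_min = fb[["row_min"]], forefoot_col_min = fb[["col_min"]],
    forefoot_row_max = fb[["row_max"]], forefoot_col_max = fb[["col_max"]],
    hindfoot_row_min = hb[["row_min"]], hindfoot_col_min = hb[["col_min"]],
    hindfoot_row_max = hb[["row_max"]], hindfoot_col_max = hb[["col_max"]]
  )
  structure(
    list(report = report, mask = mask, blobs = blobs,
         params = params, orientation = orientation),
    class = "region_report"
  )
}

#' @export
print.region_report <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<region_report> forefoot %s, hindfoot %s, ratio %.4g -> Type %d\n",
    format(r$forefoot_pressure), format(r$hindfoot_pressure),
    r$ratio, r$foot_type
  ))
  invisible(x)
}

draw_rect <- function(px, bbox, color) {
  if (anyNA(bbox)) return(px)
  r1 <- bbox[1]; c1 <- bbox[2]; r2 <- bbox[3]; c2 <- bbox[4]
  for (b in 1:3) {
    px[r1, c1:c2, b] <- color[b]
    px[r2, c1:c2, b] <- color[b]
    px[r1:r2, c1, b] <- color[b]
    px[r1:r2, c2, b] <- color[b]
  }
  px
}

#' Draw region bounding boxes on a copy of the image
#'
#' The forefoot bounding box is drawn in one fixed color and the hindfoot box
#' in another; all other pixels are untouched. The numeric report travels in a
#' JSON sidecar written by [write_region_report()].
#'
#' @param image The [pressure_image()] the report was computed from.
#' @param report A `region_report` from [analyze_pressure_image()].
#' @param forefoot_color,hindfoot_color RGB triples in `[0, 255]`.
#' @return A new annotated [pressure_image()]; the input is unchanged.
#' @export
annotate_regions <- function(image, report,
                             forefoot_color = c(0, 255, 0),
                             hindfoot_color = c(0, 128, 255)) {
  stopifnot(inherits(image, "pressure_image"), inherits(report, "region_report"))
  r <- report$report
  px <- unclass(image)
  px <- draw_rect(px, c(r$forefoot_row_min, r$forefoot_col_min,
                        r$forefoot_row_max, r$forefoot_col_max), forefoot_color)
  px <- draw_rect(px, c(r$hindfoot_row_min, r$hindfoot_col_min,
                        r$hindfoot_row_max, r$hindfoot_col_max), hindfoot_color)
  pressure_image(px)
}

#' Write a region report (with its configuration) as JSON
#'
#' @param report A `region_report`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_region_report <- function(report, path) {
  stopifnot(inherits(report, "region_report"))
  payload <- c(
    as.list(report$report),
    list(orientation = report$orientation,
         params = report$params[!vapply(report$params, is.null, logical(1))])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
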