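#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a k-means fit: one row per cluster
#'
#' @param x A `pedo_kmeans` object.
#' @param ... Unused.
#' @return A tibble with `cluster`, `size`, and centroid coordinates.
#' @method tidy pedo_kmeans
#' @export
tidy.pedo_kmeans <- function(x, ...) {
  cen <- tibble::as_tibble(as.data.frame(x$centroids), .name_repair = "minimal")
  names(cen) <- paste0("x", seq_len(ncol(cen)))
  cen$cluster <- seq_len(x$k)
  cen$size <- tabulate(x$labels, x$k)
  dplyr::select(cen, "cluster", "size", dplyr::everything())
}

#' Glance at a k-means fit
#'
#' @inheritParams tidy.pedo_kmeans
#' @return A one-row tibble: `k`, `n`, `inertia`, `iterations`.
#' @method glance pedo_kmeans
#' @export
glance.pedo_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels),
                 inertia = x$inertia, iterations = x$iterations)
}

#' Attach cluster assignments to the original data
#'
#' @param x A `pedo_kmeans` object.
#' @param data The data frame the fit was computed from.
#' @param ... Unused.
#' @return `data` as a tibble with a `.cluster` column.
#' @method augment pedo_kmeans
#' @export
augment.pedo_kmeans <- function(x, data, ...) {
  out <- tibble::as_tibble(as.data.frame(data), .name_repair = "minimal")
  out$.cluster <- x$labels
  out
}

#' Tidy a dendrogram: the merge table
#'
#' @param x A `pedo_dendrogram`.
#' @param ... Unused.
#' @return The merge tibble (`a`, `b`, `height`, `size`); negative ids denote
#'   leaves, positive ids earlier merges, as in [stats::hclust()].
#' @method tidy pedo_dendrogram
#' @export
tidy.pedo_dendrogram <- function(x, ...) x$merges

#' Glance at a dendrogram
#'
#' @inheritParams tidy.pedo_dendrogram
#' @return A one-row tibble: `n`, `linkage`, `metric`, `max_height`.
#' @method glance pedo_dendrogram
#' @export
glance.pedo_dendrogram <- function(x, ...) {
  tibble::tibble(n = x$n, linkage = x$linkage, metric = x$metric,
                 max_height = max(x$merges$height))
}

#' Tidy a region report
#'
#' @param x A `region_report` from [analyze_pressure_image()].
#' @param ... Unused.
#' @return The one-row report tibble.
#' @method tidy region_report
#' @export
tidy.region_report <- function(x, ...) x$report

#' Glance at a region report
#'
#' @inheritParams tidy.region_report
#' @return A one-row tibble: `ratio`, `foot_type`, `n_blobs`, `mask_area_px`.
#' @method glance region_report
#' @export
glance.region_report <- function(x, ...) {
  tibble::tibble(ratio = x$report$ratio, foot_type = x$report$foot_type,
                 n_blobs = nrow(x$blobs), mask_area_px = sum(x$mask))
}
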