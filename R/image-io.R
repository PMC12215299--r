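#' Construct a pressure image from a pixel array
#'
#' A pressure image is an H x W x 3 integer array of 8-bit band intensities
#' (red, green, blue), row 1 at the top of the image. This is the raw input to
#' the segmentation pipeline: in plantar pressure colormaps, deeper red encodes
#' higher pressure.
#'
#' @param pixels An H x W x 3 numeric array with values in `[0, 255]`, or an
#'   H x W matrix (interpreted as grayscale and replicated across the three
#'   bands).
#' @return A `pressure_image` object: an integer array of dimension
#'   `c(height, width, 3)`.
#' @examples
#' img <- pressure_image(array(c(200, 30, 10), dim = c(1, 1, 3)))
#' dim(img)
#' @export
pressure_image <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array or an H x W matrix", call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("band intensities must be in [0, 255] with no missing values", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "pressure_image")
}

#' @export
print.pressure_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pressure_image> %d x %d px, 3 bands (red range %d-%d)\n",
              d[1], d[2], min(x[, , 1]), max(x[, , 1])))
  invisible(x)
}

#' Read a plantar pressure image from a raster file
#'
#' Reads a PNG, TIFF or JPEG raster into a [pressure_image()]. Grayscale
#' inputs are replicated across the three bands; an alpha channel, if present,
#' is dropped with a warning (pressure-platform exports are opaque).
#'
#' @param path Path to a PNG (`.png`), TIFF (`.tif`/`.tiff`) or JPEG
#'   (`.jpg`/`.jpeg`) file.
#' @return A [pressure_image()].
#' @seealso [write_pressure_image()], [extract_band()]
#' @export
read_pressure_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read image: no such file: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
    ),
    error = function(e) {
      stop("cannot decode image file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(raw) == 0L) stop("zero-sized image: ", path, call. = FALSE)
  if (length(dim(raw)) == 3L && dim(raw)[3] %in% c(2L, 4L)) {
    warning("dropping alpha channel in ", path, call. = FALSE)
    raw <- raw[, , -dim(raw)[3], drop = FALSE]
    if (dim(raw)[3] == 1L) raw <- raw[, , 1]
  }
  if (length(dim(raw)) == 3L && dim(raw)[3] == 1L) raw <- raw[, , 1]
  pressure_image(round(raw * 255))
}

#' Write a pressure image to a raster file
#'
#' PNG and TIFF output are lossless: reading the file back reproduces the
#' pixel grid exactly.
#'
#' @param image A [pressure_image()].
#' @param path Output path; the extension (`.png`, `.tif`/`.tiff`) selects the
#'   format.
#' @return `path`, invisibly.
#' @export
write_pressure_image <- function(image, path) {
  stopifnot(inherits(image, "pressure_image"))
  arr <- unclass(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(arr, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(arr, where = path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Extract one color band from a pressure image
#'
#' Each band is a two-dimensional intensity matrix; the red band carries the
#' pressure signal in plantar pressure colormaps.
#'
#' @param image A [pressure_image()].
#' @param band One of `"red"`, `"green"`, `"blue"`.
#' @return An H x W integer matrix with values in `[0, 255]`.
#' @export
extract_band <- function(image, band = c("red", "green", "blue")) {
  stopifnot(inherits(image, "pressure_image"))
  band <- match.arg(band)
  image[, , match(band, c("red", "green", "blue"))]
}
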