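#' RGB raster image
#'
#' Wraps an H x W x 3 array of 8-bit channel values (red, green, blue) as
#' the pipeline's input type. Values must lie in [0, 255]. A greyscale
#' matrix is promoted to RGB by channel replication.
#'
#' @param pixels numeric H x W x 3 array (or H x W matrix, replicated to
#'   three channels) with values in [0, 255].
#' @return An `rgb_image` object (integer array with class attribute).
#' @export
rgb_image <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array or an H x W matrix")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' Single-channel 8-bit raster
#'
#' @param pixels numeric H x W matrix with values in [0, 255].
#' @return A `grey_image` object (integer matrix with class attribute).
#' @export
grey_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("grey values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "grey_image")
}

#' Binary foreground mask
#'
#' @param pixels logical H x W matrix; `TRUE` marks cyst-candidate
#'   foreground.
#' @return A `binary_mask` object (logical matrix with class attribute).
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (anyNA(pixels)) stop("mask must not contain NA")
  storage.mode(pixels) <- "logical"
  structure(pixels, class = "binary_mask")
}

img_height <- function(x) dim(x)[1]
img_width  <- function(x) dim(x)[2]

as_grey_matrix <- function(x) {
  m <- unclass(x)
  storage.mode(m) <- "double"
  m
}

as_mask_matrix <- function(x) {
  m <- unclass(x)
  storage.mode(m) <- "logical"
  m
}

#' Read an image file as an `rgb_image`
#'
#' Supports 8-bit PNG, TIFF and JPEG. Greyscale images are promoted to RGB
#' by channel replication; an alpha channel, if present, is dropped.
#'
#' @param path file path; format inferred from the extension.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: '", ext, "'")
  )
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) a <- a[, , 1:3] else
    if (length(dim(a)) == 3L) a <- a[, , 1L]
  rgb_image(round(a * 255))
}

#' Write a binary mask as a PNG file
#'
#' Foreground pixels are written white, background black.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask_matrix(mask) * 1, path)
  invisible(path)
}

#' Convert an RGB image to its grey-level (luminance) version
#'
#' Uses the standard Rec. 601 luminance weights
#' 0.299 R + 0.587 G + 0.114 B, rounded to the nearest integer. This is the
#' grey version used by the texture descriptor, distinct from the green
#' channel used by segmentation.
#'
#' @param image an [rgb_image()].
#' @return A [grey_image()].
#' @export
to_grey <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  a <- unclass(image)
  ch <- function(i) matrix(a[, , i], dim(a)[1], dim(a)[2])
  grey_image(round(0.299 * ch(1) + 0.587 * ch(2) + 0.114 * ch(3)))
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d px>\n", img_width(x), img_height(x)))
  invisible(x)
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image %d x %d px, mean %.2f>\n",
              img_width(x), img_height(x), mean(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d px, %d foreground>\n",
              img_width(x), img_height(x), sum(x)))
  invisible(x)
}
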