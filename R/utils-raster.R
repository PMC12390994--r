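# Raster conventions used throughout the package:
#   * images are numeric arrays [row, col, channel] with values in [0, 1]
#     (the layout png::readPNG returns);
#   * masks are integer matrices [row, col] with values in {0, 1}, where
#     1 is the panicle (foreground) class.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Coerce a raster to a binary {0,1} mask
#'
#' Accepts logical, 0/1, or 0/255 encodings (any nonzero value maps to the
#' panicle class) and returns an integer matrix with values in `{0, 1}`.
#'
#' @param x A matrix or 2-d array.
#' @return Integer matrix of 0s and 1s with the same dimensions as `x`.
#' @export
as_binary_mask <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 2L) {
    abort("`x` must be a matrix (a single-channel raster).")
  }
  m <- matrix(as.integer(x != 0), nrow = nrow(x), ncol = ncol(x))
  m
}

check_mask <- function(mask, arg = "mask") {
  if (is.null(dim(mask)) || length(dim(mask)) != 2L) {
    abort(sprintf("`%s` must be a matrix.", arg))
  }
  if (length(mask) == 0L) abort(sprintf("`%s` is empty.", arg))
  if (!all(mask %in% c(0L, 1L))) {
    abort(sprintf("`%s` must contain only values 0 and 1.", arg))
  }
  invisible(mask)
}

check_image <- function(image, arg = "image") {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    abort(sprintf("`%s` must be an [H, W, 3] RGB array.", arg))
  }
  invisible(image)
}

#' Resize a raster
#'
#' Bilinear interpolation for continuous imagery, nearest-neighbour for
#' masks (which must stay binary). Works on `[H, W]` matrices and
#' `[H, W, 3]` arrays.
#'
#' @param x Matrix or 3-d array.
#' @param height,width Target size in pixels.
#' @param method `"bilinear"` or `"nearest"`.
#' @return Resized raster of the same kind as the input.
#' @export
resize_raster <- function(x, height, width, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  filt <- if (method == "bilinear") "bilinear" else "none"
  # EBImage's first dimension corresponds to our row dimension as long as we
  # are consistent, so no transposition is needed.
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(x), w = height, h = width, filter = filt
  ))
  if (is.matrix(x) && method == "nearest") out <- as_binary_mask(round(out))
  if (!is.matrix(x)) out <- array(clamp01(out), dim = c(height, width, dim(x)[3]))
  out
}

#' Read and write masks and images as PNG
#'
#' Masks are written single-channel with 255 encoding the panicle class and
#' read back to `{0, 1}`; images are written as 8-bit RGB.
#'
#' @param path File path.
#' @param mask Binary matrix.
#' @param image `[H, W, 3]` array in `[0, 1]`.
#' @return `read_mask_png()` a binary matrix; `read_image_png()` an RGB
#'   array; the writers return `path` invisibly.
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  as_binary_mask(round(x))
}

#' @rdname raster_io
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3]
  x
}

#' @rdname raster_io
#' @export
write_image_png <- function(image, path) {
  check_image(image)
  png::writePNG(clamp01(image), path)
  invisible(path)
}
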