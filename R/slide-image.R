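#' Construct a slide image
#'
#' A slide image is the unit of analysis: one pathologist-designated
#' rectangular region of interest (pROI) exported from a whole slide image,
#' held as an 8-bit RGB raster.
#'
#' @param pixels numeric or integer array of dimension height x width x 3,
#'   values in 0..255.
#' @param slide_id character identifier.
#' @return An object of class `slide_image` with fields `slide_id` and
#'   `pixels` (integer array, height x width x 3).
#' @export
slide_image <- function(pixels, slide_id = "slide") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a height x width x 3 array")
  }
  if (any(dim(pixels)[1:2] < 1L)) stop("image dimensions must be >= 1")
  px <- array(as.integer(round(pixels)), dim = dim(pixels))
  if (min(px) < 0L || max(px) > 255L) {
    stop("pixel values must lie in 0..255")
  }
  structure(
    list(slide_id = as.character(slide_id), pixels = px),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image '%s'> %d x %d px, 3-channel 8-bit RGB\n",
              x$slide_id, d[1], d[2]))
  invisible(x)
}

img_height <- function(image) dim(image$pixels)[1]
img_width <- function(image) dim(image$pixels)[2]

# pixels as doubles in [0, 1]
img_unit <- function(image) image$pixels / 255

#' Read a slide image from PNG or TIFF
#'
#' Alpha channels are dropped, grayscale rasters are promoted to three
#' identical channels, and 16-bit samples are reduced to 8 bit by dropping
#' the low byte (with a message, since scanner exports vary).
#'
#' @param path path to a PNG or TIFF file.
#' @param slide_id identifier; defaults to the file name without extension.
#' @return A [slide_image()].
#' @export
read_image <- function(path, slide_id = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)           # doubles in [0, 1], any bit depth
    px <- round(raw * 255)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)   # doubles in [0, 1]
    bits <- attr(raw, "bits.per.sample") %||% 8L
    px <- round(unclass(raw) * (2^bits - 1))
    if (bits > 8L) {
      message("read_image: ", bits, "-bit TIFF '", basename(path),
              "' rescaled to 8-bit by dropping the low byte")
      px <- px %/% 2^(bits - 8L)
    }
    dim(px) <- dim(raw)
  } else {
    stop("unsupported image format '", ext, "' for: ", path,
         " (expected PNG or TIFF)")
  }
  if (is.matrix(px)) px <- array(px, dim = c(dim(px), 1L))
  nc <- dim(px)[3]
  if (nc == 1L) {
    px <- array(px[, , c(1, 1, 1)], dim = c(dim(px)[1:2], 3L))
  } else if (nc >= 4L) {
    px <- px[, , 1:3, drop = FALSE]
  } else if (nc == 2L) {            # gray + alpha
    px <- array(px[, , c(1, 1, 1)], dim = c(dim(px)[1:2], 3L))
  }
  slide_image(px, slide_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a slide image as lossless PNG
#'
#' @param image a [slide_image()].
#' @param path output path (".png").
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "slide_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Write a binary mask as 1-bit-style PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path path written by [write_mask()].
#' @return logical matrix (`TRUE` = foreground).
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw > 0.5
}
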