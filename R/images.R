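#' Grayscale and binary image objects
#'
#' Images are stored as plain numeric matrices (rows = image rows, columns =
#' image columns) carrying a lightweight S3 class. A `gray_image` holds
#' intensities in \[0, 255\]; a `binary_image` holds exactly 0 (black) and
#' 1 (white).
#'
#' @param x a numeric matrix, or for [as_gray_image()] a 3-dimensional RGB(A)
#'   array as returned by [png::readPNG()].
#' @return a `gray_image` or `binary_image` matrix.
#' @examples
#' img <- as_gray_image(matrix(0:255, 16, 16))
#' bw  <- as_binary_image(matrix(c(0, 1), 4, 4))
#' @export
as_gray_image <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    return(to_grayscale(x))
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or an RGB array", call. = FALSE)
  }
  if (length(x) == 0) stop("image has no pixels", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    stop("gray_image intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(unclass(x), class = c("gray_image", "matrix", "array"))
}

#' @rdname as_gray_image
#' @export
as_binary_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (length(x) == 0) stop("image has no pixels", call. = FALSE)
  if (!all(x %in% c(0, 1))) {
    stop("binary_image values must be exactly 0 or 1", call. = FALSE)
  }
  structure(unclass(x), class = c("binary_image", "matrix", "array"))
}

#' @exportS3Method base::print
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d pixels, intensity range [%g, %g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @exportS3Method base::print
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d pixels, %d white (%.1f%%)\n",
              nrow(x), ncol(x), sum(x == 1), 100 * mean(x == 1)))
  invisible(x)
}

#' Read and write images
#'
#' Reads PNG or JPEG rasters (8-bit gray or RGB) into a [gray_image][as_gray_image]
#' on the 0--255 scale; RGB inputs are converted with [to_grayscale()]. TIFF is
#' not supported in this build (no TIFF reader is available) and raises an
#' informative error.
#'
#' @param path file path; format is chosen by extension.
#' @param image a `gray_image` or `binary_image` (written as 0/255).
#' @return [read_image()] returns a `gray_image`; [write_image()] returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = stop("TIFF is not supported in this build; convert to PNG", call. = FALSE),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 3) {
    to_grayscale(raw * 255)
  } else {
    as_gray_image(round(raw * 255))
  }
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  m <- unclass(image)
  if (inherits(image, "binary_image")) m <- m * 255
  png::writePNG(pmin(pmax(m / 255, 0), 1), target = path)
  invisible(path)
}
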