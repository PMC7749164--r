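#' Preprocessing configuration
#'
#' Bundles the image-processing choices applied before a filtration: trimming
#' to a fixed window (removing scale bars and borders), multilevel wavelet
#' reconstruction (removing uneven illumination), Otsu binarization, and
#' morphological erosion of the white set.
#'
#' @param trim_width,trim_height target window in pixels (defaults 1400 x 1200,
#'   the microscope frame net of its scale bar). Set both to `NULL` to skip
#'   trimming.
#' @param wavelet_levels integer vector within 0..10 of resolution levels kept
#'   in the wavelet reconstruction (0 = coarsest approximation, 10 = finest
#'   detail), or `NULL` to skip the wavelet step.
#' @param erosion_iterations non-negative integer; erosion repetitions with a
#'   3x3 cross element.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(trim_width = 1400, trim_height = 1200,
                              wavelet_levels = NULL, erosion_iterations = 0) {
  if (!is.null(wavelet_levels)) {
    wavelet_levels <- as.integer(wavelet_levels)
    if (any(wavelet_levels < 0L | wavelet_levels > 10L)) {
      stop("wavelet_levels must lie within 0..10", call. = FALSE)
    }
  }
  if (length(erosion_iterations) != 1 || is.na(erosion_iterations) ||
      erosion_iterations < 0) {
    stop("erosion_iterations must be a single non-negative integer", call. = FALSE)
  }
  structure(
    list(trim_width = trim_width, trim_height = trim_height,
         wavelet_levels = wavelet_levels,
         erosion_iterations = as.integer(erosion_iterations)),
    class = "preprocess_config"
  )
}

#' Convert an image to grayscale
#'
#' RGB rasters are converted with the ITU-R BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B) and rounded to integer intensities, matching
#' the behaviour of the common 8-bit conversion routines; grayscale input is
#' returned unchanged.
#'
#' @param image a numeric matrix (already gray) or an h x w x 3(4) array with
#'   channels on the 0--255 scale.
#' @return a [gray_image][as_gray_image].
#' @examples
#' red <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(red)  # 76
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) {
    if (length(image) == 0) stop("image has no pixels", call. = FALSE)
    return(as_gray_image(image))
  }
  d <- dim(image)
  if (length(d) != 3 || d[3] < 3) {
    stop("expected a gray matrix or an RGB array", call. = FALSE)
  }
  if (d[1] == 0 || d[2] == 0) stop("image has no pixels", call. = FALSE)
  ch <- function(i) matrix(image[, , i], d[1], d[2])
  g <- 0.299 * ch(1) + 0.587 * ch(2) + 0.114 * ch(3)
  as_gray_image(round(g))
}

#' Trim an image to a fixed window
#'
#' Returns the top-left `height` x `width` window; used to delete the
#' microscope scale bar. The top-left anchor is a fixed convention.
#'
#' @param image a [gray_image][as_gray_image].
#' @param width,height target size in pixels.
#' @return a `gray_image` of exactly `height` rows and `width` columns.
#' @export
trim_image <- function(image, width = 1400, height = 1200) {
  if (nrow(image) < height || ncol(image) < width) {
    stop(sprintf("image (%d x %d) is smaller than the %d x %d trim target",
                 nrow(image), ncol(image), height, width), call. = FALSE)
  }
  as_gray_image(unclass(image)[seq_len(height), seq_len(width), drop = FALSE])
}

# one level of the 1D Haar transform along the rows of `m` (operates on pairs
# of adjacent rows); odd lengths are padded by repeating the last row
haar_step_rows <- function(m) {
  n <- nrow(m)
  if (n %% 2 == 1) m <- rbind(m, m[n, , drop = FALSE])
  odd <- m[seq(1, nrow(m), by = 2), , drop = FALSE]
  even <- m[seq(2, nrow(m), by = 2), , drop = FALSE]
  list(lo = (odd + even) / sqrt(2), hi = (odd - even) / sqrt(2))
}

haar_inverse_rows <- function(lo, hi, n_orig) {
  odd <- (lo + hi) / sqrt(2)
  even <- (lo - hi) / sqrt(2)
  out <- matrix(0, 2 * nrow(lo), ncol(lo))
  out[seq(1, nrow(out), by = 2), ] <- odd
  out[seq(2, nrow(out), by = 2), ] <- even
  out[seq_len(n_orig), , drop = FALSE]
}

#' Multilevel Haar wavelet reconstruction
#'
#' Decomposes the image with a 10-level separable 2D Haar (Daubechies-1)
#' transform and reconstructs it using only the requested resolution levels.
#' Level 0 is the coarsest (the final approximation band, carrying smooth
#' brightness disproportion); levels 1..10 are detail bands from coarsest to
#' finest. Coefficients at levels outside `levels` are zeroed before the
#' inverse transform; the result is clipped to \[0, 255\].
#'
#' Removing the coarse levels (e.g. keeping levels 4--10) flattens uneven
#' illumination while keeping the texture detail.
#'
#' @param image a [gray_image][as_gray_image].
#' @param levels integer vector within 0..10; levels to keep. An empty vector
#'   yields an all-zero image.
#' @param n_levels decomposition depth (default 10).
#' @return a `gray_image` of the same size.
#' @export
wavelet_reconstruct <- function(image, levels, n_levels = 10) {
  levels <- as.integer(levels)
  if (any(levels < 0L | levels > n_levels)) {
    stop("levels must lie within 0..", n_levels, call. = FALSE)
  }
  a <- unclass(image)
  details <- vector("list", n_levels)
  sizes <- vector("list", n_levels)
  for (l in seq_len(n_levels)) {
    sizes[[l]] <- dim(a)
    rowd <- haar_step_rows(a)
    lo_lo <- haar_step_rows(t(rowd$lo))
    hi_lo <- haar_step_rows(t(rowd$hi))
    # bands stored transposed (columns transformed via t())
    details[[l]] <- list(lh = lo_lo$hi, hl = hi_lo$lo, hh = hi_lo$hi)
    a <- t(lo_lo$lo)
  }
  # level numbering: decomposition step l holds detail level (n_levels + 1 - l)
  if (!(0L %in% levels)) a <- a * 0
  for (l in rev(seq_len(n_levels))) {
    det <- details[[l]]
    keep <- (n_levels + 1L - l) %in% levels
    if (!keep) det <- lapply(det, function(m) m * 0)
    sz <- sizes[[l]]
    lo_t <- haar_inverse_rows(t(a), det$lh, sz[2])      # undo the column step
    hi_t <- haar_inverse_rows(det$hl, det$hh, sz[2])
    a <- haar_inverse_rows(t(lo_t), t(hi_t), sz[1])     # undo the row step
  }
  as_gray_image(pmin(pmax(a, 0), 255))
}

#' Otsu binarization
#'
#' Picks the threshold maximizing between-class variance over the 256-bin
#' intensity histogram; pixels strictly above the threshold become white (1).
#' Ties are broken toward the smallest maximizing threshold. A constant image
#' is degenerate: the threshold equals the constant, so the result is all
#' black.
#'
#' @param image a [gray_image][as_gray_image].
#' @return a list with elements `binary` (a [binary_image][as_binary_image])
#'   and `threshold`.
#' @export
binarize_otsu <- function(image) {
  v <- pmin(pmax(round(unclass(image)), 0), 255)
  counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)
  w1 <- n - w0
  mu0 <- cumsum(counts * lev) / pmax(w0, 1)
  mu1 <- (sum(counts * lev) - cumsum(counts * lev)) / pmax(w1, 1)
  sigma_b <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- 0
  if (max(sigma_b) == 0) {
    t_star <- v[1, 1]  # constant image: threshold at the constant, all black
  } else {
    t_star <- lev[which.max(sigma_b)]  # which.max takes the first maximum
  }
  bin <- as_binary_image((v > t_star) + 0)
  list(binary = bin, threshold = as.numeric(t_star))
}

#' Morphological erosion of the white set
#'
#' Erodes the white (1) pixels with a 3x3 cross structuring element, applied
#' `iterations` times; pixels outside the image are treated as black, so the
#' white set never grows and border whites are removed.
#'
#' @param image a [binary_image][as_binary_image].
#' @param iterations non-negative integer.
#' @return a `binary_image`.
#' @export
erode_binary <- function(image, iterations = 1) {
  if (length(iterations) != 1 || is.na(iterations) || iterations < 0) {
    stop("iterations must be a single non-negative integer", call. = FALSE)
  }
  out <- cpp_erode_cross(matrix(as.integer(image), nrow(image)), as.integer(iterations))
  as_binary_image(out + 0)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: grayscale conversion, trimming (skipped when the config
#' has `trim_width = NULL` or the image already matches the window), wavelet
#' reconstruction (when `wavelet_levels` is set), Otsu binarization, and
#' erosion.
#'
#' @param image a raster accepted by [to_grayscale()].
#' @param config a [preprocess_config()].
#' @return a list with `gray` (the processed [gray_image][as_gray_image]),
#'   `binary` (a [binary_image][as_binary_image]) and `threshold`.
#' @export
preprocess_image <- function(image, config = preprocess_config()) {
  g <- to_grayscale(image)
  if (!is.null(config$trim_width) && !is.null(config$trim_height)) {
    g <- trim_image(g, config$trim_width, config$trim_height)
  }
  if (!is.null(config$wavelet_levels)) {
    g <- wavelet_reconstruct(g, config$wavelet_levels)
  }
  ot <- binarize_otsu(g)
  b <- ot$binary
  if (config$erosion_iterations > 0) {
    b <- erode_binary(b, config$erosion_iterations)
  }
  list(gray = g, binary = b, threshold = ot$threshold)
}
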