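#' Filtration fields
#'
#' A filtration field assigns a real value to every node of a pixel grid; its
#' superlevel sets (the region above a decreasing threshold) are what the
#' persistence computation tracks. Fields carry their `spacing` (pixels
#' between grid nodes; node `(i, j)` sits at pixel
#' `origin + (i - 1, j - 1) * spacing`) and the name of the filtration that
#' produced them.
#'
#' @param values numeric matrix of filtration values (finite).
#' @param spacing grid spacing in pixels (>= 1).
#' @param origin pixel coordinate (row, col) of grid node (1, 1).
#' @param filtration name of the generating filtration.
#' @return a `filtration_field` object.
#' @export
filtration_field <- function(values, spacing = 1, origin = c(1, 1),
                             filtration = "custom") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("filtration values must be finite", call. = FALSE)
  if (spacing < 1) stop("spacing must be >= 1", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin,
                 filtration = filtration),
            class = "filtration_field")
}

#' @exportS3Method base::print
print.filtration_field <- function(x, ...) {
  cat(sprintf("<filtration_field: %s> %d x %d nodes, spacing %g px, range [%.4g, %.4g]\n",
              x$filtration, nrow(x$values), ncol(x$values), x$spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

# grid node pixel coordinates along one axis of length n with given spacing
grid_axis <- function(n, spacing) seq(1, n, by = spacing)

#' k-nearest-neighbour density filtration
#'
#' Estimates the density of white pixels on a coarse grid: at each node the
#' Euclidean distance \eqn{r_k} to the k-th nearest white pixel is measured and
#' converted to the standard two-dimensional kNN density
#' \eqn{f = k / (n_w \pi r_k^2)} with \eqn{n_w} the white pixel count. Nodes
#' coinciding with white pixels (where \eqn{r_k = 0}) are capped by
#' substituting the smallest positive \eqn{r_k} observed on the grid, keeping
#' the field finite.
#'
#' @param image a [binary_image][as_binary_image] with at least `k` white pixels.
#' @param k number of neighbours (default 100).
#' @param spacing grid spacing in pixels (default 10).
#' @return a [filtration_field()] (`filtration = "knn"`), suitable for
#'   log-scaling after persistence since all values are positive.
#' @export
knn_density <- function(image, k = 100, spacing = 10) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  white <- which(unclass(image) == 1, arr.ind = TRUE)
  n_white <- nrow(white)
  if (n_white < k) {
    stop(sprintf("kNN density needs at least k = %d white pixels, image has %d",
                 k, n_white), call. = FALSE)
  }
  rows <- grid_axis(nrow(image), spacing)
  cols <- grid_axis(ncol(image), spacing)
  grid <- cbind(rep(rows, times = length(cols)),
                rep(cols, each = length(rows)))
  nn <- FNN::get.knnx(white, grid, k = k)
  r_k <- nn$nn.dist[, k]
  if (any(r_k == 0)) {
    pos <- r_k[r_k > 0]
    r_k[r_k == 0] <- if (length(pos)) min(pos) else 1
  }
  dens <- k / (n_white * pi * r_k^2)
  filtration_field(matrix(dens, nrow = length(rows), ncol = length(cols)),
                   spacing = spacing, filtration = "knn")
}

#' Manhattan signed distance filtration
#'
#' White pixels get the positive Manhattan (city-block) distance to the
#' nearest black pixel; black pixels get minus the distance to the nearest
#' white pixel. A white pixel 4-adjacent to black is +1 and vice versa. A
#' one-colour image is degenerate and gets the sentinel
#' `+(width + height)` (all white) or `-(width + height)` (all black).
#'
#' @param image a [binary_image][as_binary_image].
#' @return a [filtration_field()] at pixel resolution (`filtration = "signed"`).
#' @export
signed_distance <- function(image) {
  m <- unclass(image)
  sentinel <- nrow(m) + ncol(m)
  if (all(m == 1)) {
    return(filtration_field(m * 0 + sentinel, filtration = "signed"))
  }
  if (all(m == 0)) {
    return(filtration_field(m * 0 - sentinel, filtration = "signed"))
  }
  d_to_black <- cpp_l1_distance(m == 0)
  d_to_white <- cpp_l1_distance(m == 1)
  vals <- ifelse(m == 1, d_to_black, -d_to_white)
  filtration_field(vals, filtration = "signed")
}

#' Grayscale filtration
#'
#' Uses the 8-bit intensity itself as the filtration value (255 = white enters
#' the superlevel set first), at pixel resolution.
#'
#' @param image a [gray_image][as_gray_image].
#' @return a [filtration_field()] (`filtration = "gray"`).
#' @export
grayscale_filtration <- function(image) {
  filtration_field(unclass(image) + 0, filtration = "gray")
}

#' Compute a filtration field from a preprocessed image
#'
#' Dispatcher used by the pipeline: `"knn"` and `"signed"` consume the binary
#' image, `"gray"` the grayscale one.
#'
#' @param prep result of [preprocess_image()].
#' @param filtration one of `"knn"`, `"signed"`, `"gray"`.
#' @param k,spacing kNN parameters (see [knn_density()]).
#' @return a [filtration_field()].
#' @export
compute_filtration <- function(prep, filtration = c("knn", "signed", "gray"),
                               k = 100, spacing = 10) {
  filtration <- match.arg(filtration)
  switch(filtration,
         knn = knn_density(prep$binary, k = k, spacing = spacing),
         signed = signed_distance(prep$binary),
         gray = grayscale_filtration(prep$gray))
}
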