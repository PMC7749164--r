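#' Fit a diagram vectorizer on training diagrams
#'
#' Fixes, from the training set only, the dynamic range of the
#' mid-life/life-time plane (per homology dimension), the maximum life-time
#' used by the persistence-image weighting, and the partition of that range
#' into a `grid` of regions. The fitted configuration is then applied
#' unchanged to test diagrams, which prevents information leaking from test
#' to train.
#'
#' @param diagrams list of [compute_persistence()] results (the training set).
#' @param method `"persistence_image"` or `"counts"`.
#' @param grid regions per axis, default `c(20, 20)` (mid-life x life-time).
#' @param sigma Gaussian standard deviation for the persistence image
#'   (the study compares 0.1 and 1; default 0.1).
#' @param dims homology dimensions embedded, default `c(0, 1)`.
#' @return a `pd_vectorizer` with per-dim ranges, `weight_max`, and the region
#'   edges. Degenerate (zero-width) ranges are expanded by a fixed 5% margin.
#' @export
fit_vectorizer <- function(diagrams, method = c("persistence_image", "counts"),
                           grid = c(20, 20), sigma = 0.1, dims = c(0, 1)) {
  method <- match.arg(method)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  pts <- dplyr::bind_rows(purrr::map(diagrams, as_midlife_lifetime))
  if (nrow(pts) == 0) {
    stop("cannot fit a vectorizer on an all-empty training set", call. = FALSE)
  }
  expand_degenerate <- function(rng) {
    if (diff(rng) > 0) return(rng)
    m <- 0.05 * max(abs(rng[1]), 1)
    rng + c(-m, m)
  }
  ranges <- purrr::map(dims, function(d) {
    p <- dplyr::filter(pts, .data$dim == d)
    if (nrow(p) == 0) {
      list(mid = c(0, 1), life = c(0, 1))  # unseen dim: unit box placeholder
    } else {
      list(mid = expand_degenerate(range(p$mid_life)),
           life = expand_degenerate(range(p$life_time)))
    }
  })
  names(ranges) <- paste0("dim", dims)
  structure(
    list(method = method, grid = as.integer(grid), sigma = sigma, dims = dims,
         ranges = ranges, weight_max = max(pts$life_time)),
    class = "pd_vectorizer"
  )
}

#' @exportS3Method base::print
print.pd_vectorizer <- function(x, ...) {
  cat(sprintf("<pd_vectorizer: %s> %dx%d regions per dim, sigma %g, weight_max %.4g\n",
              x$method, x$grid[1], x$grid[2], x$sigma, x$weight_max))
  invisible(x)
}

region_edges <- function(rng, n) seq(rng[1], rng[2], length.out = n + 1)

# half-open [low, high) region assignment, last region closed, out-of-range
# points clipped to the boundary regions
region_index <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

vector_names <- function(dims, grid) {
  unlist(purrr::map(dims, function(d) {
    as.vector(outer(seq_len(grid[1]), seq_len(grid[2]),
                    function(r, c) sprintf("pd%d_r%02d_c%02d", d, r, c)))
  }))
}

count_block <- function(p, rng, grid) {
  if (nrow(p) == 0) return(numeric(prod(grid)))
  i <- region_index(p$mid_life, region_edges(rng$mid, grid[1]))
  j <- region_index(p$life_time, region_edges(rng$life, grid[2]))
  tabulate((j - 1L) * grid[1] + i, nbins = prod(grid)) + 0
}

# closed-form region masses: separable Gaussian CDF differences per axis
image_block <- function(p, rng, grid, sigma, weight_max) {
  if (nrow(p) == 0) return(numeric(prod(grid)))
  xe <- region_edges(rng$mid, grid[1])
  ye <- region_edges(rng$life, grid[2])
  w <- pmin(pmax(p$life_time / weight_max, 0), 1)
  dx <- t(apply(pnorm(outer(-p$mid_life, xe, "+") / sigma), 1, diff))
  dy <- t(apply(pnorm(outer(-p$life_time, ye, "+") / sigma), 1, diff))
  if (nrow(p) == 1) { dx <- matrix(dx, 1); dy <- matrix(dy, 1) }
  as.vector(crossprod(dx * w, dy))
}

#' Vectorize a persistence diagram
#'
#' Embeds a diagram into a fixed-length non-negative vector under a fitted
#' [fit_vectorizer()] configuration. With `method = "counts"` each entry is
#' the number of (mid-life, life-time) points in the region (half-open region
#' boundaries, last region closed, out-of-range points clipped to boundary
#' regions). With `method = "persistence_image"` each point contributes an
#' isotropic Gaussian scaled by the linear weight
#' `life_time / weight_max` (clipped to \[0, 1\]: zero at the x-axis, one at
#' the maximum training life-time), integrated in closed form over each
#' region. The dim-0 block comes first, then dim 1, 400 entries each for the
#' default 20 x 20 grid.
#'
#' @param diagram a [compute_persistence()] result.
#' @param config a fitted `pd_vectorizer`.
#' @return a named numeric vector of length `prod(grid) * length(dims)`.
#' @export
vectorize_diagram <- function(diagram, config) {
  pts <- as_midlife_lifetime(diagram)
  blocks <- purrr::map(seq_along(config$dims), function(i) {
    d <- config$dims[i]
    p <- dplyr::filter(pts, .data$dim == d)
    rng <- config$ranges[[paste0("dim", d)]]
    if (config$method == "counts") {
      count_block(p, rng, config$grid)
    } else {
      image_block(p, rng, config$grid, config$sigma, config$weight_max)
    }
  })
  setNames(unlist(blocks), vector_names(config$dims, config$grid))
}

#' Build a feature matrix for a cohort of diagrams
#'
#' @param diagrams named list of diagrams; names are image ids.
#' @param config a fitted [fit_vectorizer()].
#' @return a tibble with `image_id` and one column per diagram region.
#' @export
diagram_features <- function(diagrams, config) {
  rows <- purrr::map(diagrams, vectorize_diagram, config = config)
  out <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble::tibble(image_id = names(diagrams)), out)
}

#' Drop near-zero-variance feature columns
#'
#' Applies the standard near-zero-variance filter to count (or image)
#' features: a column is dropped when it is constant, or when the ratio of
#' its most frequent to second most frequent value exceeds `freq_cut`
#' (default 95/5) while the fraction of distinct values is below
#' `unique_cut` (default 10%).
#'
#' @param data a tibble/data frame of feature columns (non-feature columns can
#'   be protected via `protect`).
#' @param freq_cut,unique_cut filter parameters.
#' @param protect character vector of column names never dropped.
#' @return a list with `data` (the reduced tibble) and `kept` (retained
#'   feature column names).
#' @export
drop_near_zero_variance <- function(data, freq_cut = 95 / 5, unique_cut = 0.1,
                                    protect = character()) {
  if (nrow(data) < 2) stop("need at least 2 rows", call. = FALSE)
  is_nzv <- function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1) return(TRUE)
    ratio <- tab[1] / tab[2]
    ratio > freq_cut && (length(tab) / length(x)) < unique_cut
  }
  cand <- setdiff(names(data), protect)
  drop <- cand[purrr::map_lgl(data[cand], is_nzv)]
  kept <- setdiff(cand, drop)
  list(data = data[, setdiff(names(data), drop), drop = FALSE], kept = kept)
}
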