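#' Mid-life / life-time coordinates
#'
#' Re-expresses each persistence pair by its mid-life `(birth + death) / 2`
#' (the threshold regime where the feature lives) and its life-time
#' `birth - death` (its robustness). The essential component is excluded by
#' default because its death is a sentinel, not a measured merge.
#'
#' @param diagram a [compute_persistence()] result.
#' @param include_essential keep the essential pair (default `FALSE`).
#' @return a tibble with columns `dim`, `mid_life`, `life_time` and the
#'   generator positions carried over.
#' @export
as_midlife_lifetime <- function(diagram, include_essential = FALSE) {
  d <- tibble::as_tibble(diagram)
  if (!include_essential) d <- dplyr::filter(d, !.data$essential)
  dplyr::transmute(d,
    dim = .data$dim,
    mid_life = (.data$birth + .data$death) / 2,
    life_time = .data$birth - .data$death,
    birth_row = .data$birth_row, birth_col = .data$birth_col,
    death_row = .data$death_row, death_col = .data$death_col)
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
sd_or_conv <- function(x) {
  if (length(x) == 0) return(NA_real_)
  if (length(x) == 1) return(0)        # singleton convention
  sd(x)                                # sample sd, n - 1 denominator
}

#' Scalar topology summaries of a diagram
#'
#' Computes the ten per-image topology summaries used in the univariate
#' screen: counts of connected components and holes, plus mean and sample
#' standard deviation of mid-life and life-time for each dimension.
#' `n_components` counts all 0-dim pairs including the essential one (every
#' connected component is a component); the essential pair is excluded from
#' the mean/sd statistics, whose death value is a sentinel. A dimension with
#' no pairs yields `NA` summaries; a singleton yields sd 0.
#'
#' @param diagram a [compute_persistence()] result.
#' @return a one-row tibble with columns `n_components`, `n_holes`,
#'   `mean_midlife_0`, `sd_midlife_0`, `mean_lifetime_0`, `sd_lifetime_0` and
#'   the same four for dimension 1.
#' @export
summarize_diagram <- function(diagram) {
  pts <- as_midlife_lifetime(diagram, include_essential = FALSE)
  p0 <- dplyr::filter(pts, .data$dim == 0)
  p1 <- dplyr::filter(pts, .data$dim == 1)
  tibble::tibble(
    n_components = sum(diagram$dim == 0),
    n_holes = sum(diagram$dim == 1),
    mean_midlife_0 = mean_or_na(p0$mid_life),
    sd_midlife_0 = sd_or_conv(p0$mid_life),
    mean_lifetime_0 = mean_or_na(p0$life_time),
    sd_lifetime_0 = sd_or_conv(p0$life_time),
    mean_midlife_1 = mean_or_na(p1$mid_life),
    sd_midlife_1 = sd_or_conv(p1$mid_life),
    mean_lifetime_1 = mean_or_na(p1$life_time),
    sd_lifetime_1 = sd_or_conv(p1$life_time)
  )
}

#' Topology summaries for a whole cohort of images
#'
#' Maps [image_persistence()] and [summarize_diagram()] over a list of images
#' and binds the rows to the cohort table, giving the input for
#' [univariate_screen()].
#'
#' @param images named list of rasters; names are image ids.
#' @param cohort a cohort tibble with an `image_id` column (see
#'   [generate_cohort()]).
#' @inheritParams image_persistence
#' @return the cohort tibble with the ten topology columns appended.
#' @export
cohort_summaries <- function(images, cohort, filtration = "knn",
                             config = preprocess_config(trim_width = NULL),
                             k = 100, spacing = 10) {
  sums <- purrr::map(cohort$image_id, function(id) {
    summarize_diagram(image_persistence(images[[id]], filtration,
                                        config = config, k = k,
                                        spacing = spacing))
  })
  dplyr::bind_cols(cohort, dplyr::bind_rows(sums))
}
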