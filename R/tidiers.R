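#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for fitted objects
#'
#' `tidy()` returns per-term or per-observation tibbles; `glance()` returns a
#' one-row model-level summary, following the broom conventions.
#'
#' @param x a `tewl_screen`, `skintda_model` or `tewl_report`.
#' @param ... unused.
#' @return a tibble.
#' @name skintda-tidiers
NULL

#' @rdname skintda-tidiers
#' @export
tidy.tewl_screen <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname skintda-tidiers
#' @export
tidy.skintda_model <- function(x, ...) {
  if (x$algorithm %in% c("random_forest", "gb_tree")) {
    imp <- learner_importance(x$learner)
    tibble::tibble(term = names(imp), importance = unname(imp))
  } else if (!is.null(x$cv)) {
    x$cv
  } else {
    tibble::tibble(term = x$features)
  }
}

#' @rdname skintda-tidiers
#' @export
glance.skintda_model <- function(x, ...) {
  out <- tibble::tibble(algorithm = x$algorithm, response = x$response,
                        n_features = length(x$features))
  if (!is.null(x$cv)) out$cv_rmse <- min(x$cv$cv_rmse)
  out
}

#' @rdname skintda-tidiers
#' @export
tidy.tewl_report <- function(x, ...) {
  x$predictions
}

#' @rdname skintda-tidiers
#' @export
glance.tewl_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(response = x$response, filtration = x$filtration,
                   algorithm = x$model$algorithm,
                   n_train_subjects = length(x$split$train),
                   n_test_subjects = length(x$split$test)),
    x$metrics
  )
}

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' types: diagrams in mid-life/life-time coordinates, the univariate screen's
#' t-values, region-importance heatmaps, and predicted-versus-observed
#' scatter for a pipeline report.
#'
#' @param object the object to plot.
#' @param coordinates for diagrams, `"midlife"` (default) or `"birth_death"`.
#' @param ... unused.
#' @return a ggplot.
#' @name skintda-autoplot
NULL

#' @rdname skintda-autoplot
#' @export
autoplot.persistence_diagram <- function(object,
                                         coordinates = c("midlife",
                                                         "birth_death"),
                                         ...) {
  coordinates <- match.arg(coordinates)
  if (coordinates == "midlife") {
    pts <- as_midlife_lifetime(object)
    ggplot2::ggplot(pts, ggplot2::aes(.data$mid_life, .data$life_time)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::facet_wrap(~dim, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "mid-life", y = "life-time")
  } else {
    d <- dplyr::filter(tibble::as_tibble(object), !.data$essential)
    ggplot2::ggplot(d, ggplot2::aes(.data$birth, .data$death)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::facet_wrap(~dim, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "birth", y = "death")
  }
}

#' @rdname skintda-autoplot
#' @export
autoplot.tewl_screen <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     term = factor(.data$term, levels = rev(.data$term)),
                     significant = !is.na(.data$fdr) & .data$fdr < 0.01)
  ggplot2::ggplot(d, ggplot2::aes(.data$t_value, .data$term,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "t value", y = NULL, fill = "FDR < 0.01")
}

#' @rdname skintda-autoplot
#' @export
autoplot.region_importance <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$dim))
  ggplot2::ggplot(d, ggplot2::aes(.data$region_row, .data$region_col,
                                  fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~dim, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "mid-life region", y = "life-time region")
}

#' @rdname skintda-autoplot
#' @export
autoplot.tewl_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$observed, .data$prediction)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = paste("observed", object$response),
                  y = paste("predicted", object$response))
}

#' @rdname skintda-autoplot
#' @export
autoplot.gray_image <- function(object, ...) {
  d <- tidyr::expand_grid(row = seq_len(nrow(object)),
                          col = seq_len(ncol(object)))
  d$value <- as.vector(t(unclass(object)))  # expand_grid varies col fastest
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
}
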