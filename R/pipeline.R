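#' End-to-end TEWL prediction pipeline
#'
#' Runs the full protocol on a cohort of images: preprocess, filtration,
#' persistence, vectorization (fitted on the training split only), optional
#' near-zero-variance filtering and PCA, learner training with subject-level
#' cross-validated hyperparameter choice, per-image prediction, subject-median
#' aggregation, and accuracy metrics on the held-out subjects. The default
#' configuration is the study's best performer: signed-distance filtration,
#' persistence image with sigma 0.1, no wavelet or erosion step.
#'
#' @param images named list of rasters (names = image ids).
#' @param cohort cohort tibble (see [generate_cohort()]); must contain
#'   `image_id`, `subject_id`, `session` and the response column.
#' @param response response column (`"tewl"`, `"moisture_corneometer"`, or
#'   `"moisture_skicon"`).
#' @param filtration,k,spacing see [compute_filtration()].
#' @param preprocess a [preprocess_config()].
#' @param vectorize_method,sigma see [fit_vectorizer()].
#' @param use_pca apply [pca_reduce()] to the diagram features.
#' @param pca_min_ratio minimum contribution ratio of kept components.
#' @param algorithm learner (see [fit_learner()]).
#' @param train_fraction subject fraction in training (default 0.7).
#' @param cv_folds,cv_repeats,grid hyperparameter search (see
#'   [train_model()]); pass `grid = list()` to skip tuning.
#' @param seed seed covering the split, fold assignment and stochastic fits.
#' @param diagrams optionally, precomputed diagrams (named list matching
#'   `cohort$image_id`) to skip the image stages.
#' @return a `tewl_report`: metrics, subject predictions, the fitted model,
#'   vectorizer, PCA mapping, split, and stage timings.
#' @export
tewl_pipeline <- function(images, cohort, response = "tewl",
                          filtration = "signed",
                          preprocess = preprocess_config(trim_width = NULL),
                          k = 100, spacing = 10,
                          vectorize_method = "persistence_image", sigma = 0.1,
                          use_pca = TRUE, pca_min_ratio = 0.01,
                          algorithm = "random_forest", train_fraction = 0.7,
                          cv_folds = 10, cv_repeats = 10, grid = list(),
                          seed = 1, diagrams = NULL) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  if (is.null(diagrams)) {
    missing_ids <- setdiff(cohort$image_id, names(images))
    if (length(missing_ids)) {
      stop("images missing for ids: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    diagrams <- purrr::map(setNames(cohort$image_id, cohort$image_id),
                           function(id) {
                             image_persistence(images[[id]], filtration,
                                               config = preprocess, k = k,
                                               spacing = spacing)
                           })
  }
  timings["persistence"] <- tic() - t0; t0 <- tic()

  split <- split_cohort(cohort, train_fraction, seed = seed)
  in_train <- cohort$subject_id %in% split$train
  vec_cfg <- fit_vectorizer(diagrams[cohort$image_id[in_train]],
                            method = vectorize_method, sigma = sigma)
  feats <- diagram_features(diagrams, vec_cfg)
  data <- dplyr::left_join(cohort, feats, by = "image_id")
  timings["vectorize"] <- tic() - t0; t0 <- tic()

  pd_cols <- grep("^pd[01]_", names(data), value = TRUE)
  nzv <- drop_near_zero_variance(data[in_train, pd_cols, drop = FALSE])
  pd_cols <- nzv$kept
  id_cols <- intersect(c("image_id", "subject_id", "session", "image_index",
                         response, covariate_columns(data)), names(data))
  pca <- NULL
  if (use_pca) {
    pca <- pca_reduce(data[in_train, pd_cols, drop = FALSE],
                      data[!in_train, pd_cols, drop = FALSE],
                      min_ratio = pca_min_ratio)
    train_data <- dplyr::bind_cols(data[in_train, id_cols],
                                   tibble::as_tibble(pca$train))
    test_data <- dplyr::bind_cols(data[!in_train, id_cols],
                                  tibble::as_tibble(pca$test))
  } else {
    train_data <- data[in_train, c(id_cols, pd_cols)]
    test_data <- data[!in_train, c(id_cols, pd_cols)]
  }
  timings["reduce"] <- tic() - t0; t0 <- tic()

  model <- train_model(train_data, response = response, algorithm = algorithm,
                       cv_folds = cv_folds, cv_repeats = cv_repeats,
                       grid = grid, seed = seed + 1L)
  timings["train"] <- tic() - t0; t0 <- tic()

  preds <- predict_subject(model, test_data)
  metrics <- evaluate_predictions(preds$prediction, preds$observed)
  timings["predict"] <- tic() - t0

  structure(list(metrics = metrics, predictions = preds, model = model,
                 vectorizer = vec_cfg, pca = pca, split = split,
                 nzv_kept = pd_cols, response = response,
                 filtration = filtration, train_data = train_data,
                 test_data = test_data, data = data,
                 timings = timings),
            class = "tewl_report")
}

#' @exportS3Method base::print
print.tewl_report <- function(x, ...) {
  cat(sprintf("<tewl_report: %s ~ %s persistence, %s>\n", x$response,
              x$filtration, x$model$algorithm))
  cat(sprintf("  %d train / %d test subjects\n", length(x$split$train),
              length(x$split$test)))
  m <- x$metrics
  cat(sprintf("  held-out subject-level R2 = %.3f, RMSE = %.3f, MAE = %.3f\n",
              m$r2, m$rmse, m$mae))
  invisible(x)
}

#' Diagram-region importance with back-mapping through PCA
#'
#' Repeats the split/train cycle `n_repeats` times with different random test
#' subjects, averages the learner's impurity importance per feature, and maps
#' principal-component importance back onto diagram regions as
#' `importance_j = sum_c importance(pc_c) * |loading_jc|`, normalized so all
#' importances sum to one. Without PCA, per-column importance passes through
#' unchanged (identity mapping). The feature table (and hence the vectorizer
#' ranges) is held fixed across repeats.
#'
#' @param data image-level feature table with `subject_id`, the response,
#'   `pd*` feature columns and covariates.
#' @param response response column name.
#' @param algorithm a tree learner exposing impurity importance
#'   (`random_forest` or `gb_tree`).
#' @param use_pca,pca_min_ratio see [tewl_pipeline()].
#' @param train_fraction subject fraction used for training in each repeat.
#' @param n_repeats number of split/train repeats (default 10).
#' @param params learner hyperparameters (fixed; no grid search here).
#' @param seed seed for the repeat sequence.
#' @return a `region_importance` tibble: `term`, `dim`, `region_row`
#'   (mid-life bin), `region_col` (life-time bin), `importance`; covariates
#'   appear with `NA` region coordinates.
#' @export
region_importance <- function(data, response = "tewl",
                              algorithm = "random_forest", use_pca = TRUE,
                              pca_min_ratio = 0.01, train_fraction = 0.7,
                              n_repeats = 10, params = list(), seed = NULL) {
  pd_cols <- grep("^pd[01]_", names(data), value = TRUE)
  cov_cols <- covariate_columns(data)
  y_all <- data[[response]]
  with_seed(seed, {
    acc <- setNames(numeric(length(pd_cols) + length(cov_cols)),
                    c(pd_cols, cov_cols))
    for (r in seq_len(n_repeats)) {
      split <- split_cohort(data, train_fraction)
      tr <- data$subject_id %in% split$train
      if (use_pca) {
        pca <- pca_reduce(data[tr, pd_cols, drop = FALSE],
                          min_ratio = pca_min_ratio)
        x <- cbind(pca$train, model_matrix_of(data[tr, ], cov_cols))
      } else {
        x <- model_matrix_of(data[tr, ], c(pd_cols, cov_cols))
      }
      fit <- fit_learner(x, y_all[tr], algorithm, params = params)
      imp <- learner_importance(fit)
      if (use_pca) {
        pc_names <- colnames(pca$train)
        region_imp <- drop(abs(pca$rotation) %*% imp[pc_names])
        contrib <- setNames(numeric(length(acc)), names(acc))
        contrib[pca$kept_features] <- region_imp
        contrib[cov_cols] <- imp[cov_cols]
      } else {
        contrib <- imp[names(acc)]
        contrib[is.na(contrib)] <- 0
      }
      acc <- acc + contrib
    }
    acc <- acc / n_repeats
    if (sum(acc) > 0) acc <- acc / sum(acc)
    info <- parse_region_names(names(acc))
    structure(dplyr::bind_cols(info, tibble::tibble(importance = unname(acc))),
              class = c("region_importance", class(tibble::tibble())))
  })
}

parse_region_names <- function(nm) {
  m <- regmatches(nm, regexec("^pd([01])_r(\\d+)_c(\\d+)$", nm))
  tibble::tibble(
    term = nm,
    dim = purrr::map_int(m, ~ if (length(.x)) as.integer(.x[2]) else NA_integer_),
    region_row = purrr::map_int(m, ~ if (length(.x)) as.integer(.x[3]) else NA_integer_),
    region_col = purrr::map_int(m, ~ if (length(.x)) as.integer(.x[4]) else NA_integer_)
  )
}

#' Overlay generator positions on the original image
#'
#' Marks, on the pixel raster, the generators of the persistence pairs whose
#' (mid-life, life-time) coordinates fall in a selected diagram region: birth
#' positions of connected components in red, death positions of holes (where
#' they are filled in) in blue. Grid-node coordinates are scaled back to
#' pixels through the field's grid spacing.
#'
#' @param image the [gray_image][as_gray_image] the diagram came from.
#' @param diagram its [compute_persistence()] diagram (positions intact).
#' @param region a one-row data frame or list with `dim`, `region_row`,
#'   `region_col` (e.g. a row of [region_importance()]); several rows are
#'   allowed.
#' @param config the fitted [fit_vectorizer()] defining the region grid.
#' @param mark_half_size half-size in pixels of the square marks (default 2).
#' @return an `height x width x 3` RGB array on the 0--255 scale (writable
#'   with [write_image()]).
#' @export
overlay_generators <- function(image, diagram, region, config,
                               mark_half_size = 2) {
  region <- tibble::as_tibble(region)
  pts <- as_midlife_lifetime(diagram)
  spacing <- attr(diagram, "spacing")
  origin <- attr(diagram, "origin")
  g <- unclass(image)
  rgb <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  n_marks <- 0L
  for (i in seq_len(nrow(region))) {
    d <- region$dim[i]
    rng <- config$ranges[[paste0("dim", d)]]
    xe <- region_edges(rng$mid, config$grid[1])
    ye <- region_edges(rng$life, config$grid[2])
    sel <- dplyr::filter(pts, .data$dim == d)
    sel <- sel[region_index(sel$mid_life, xe) == region$region_row[i] &
               region_index(sel$life_time, ye) == region$region_col[i], ]
    if (nrow(sel) == 0) next
    if (d == 0) {
      rr <- origin[1] + (sel$birth_row - 1) * spacing
      cc <- origin[2] + (sel$birth_col - 1) * spacing
      col <- c(255, 0, 0)
    } else {
      rr <- origin[1] + (sel$death_row - 1) * spacing
      cc <- origin[2] + (sel$death_col - 1) * spacing
      col <- c(0, 0, 255)
    }
    for (j in seq_along(rr)) {
      ri <- pmax(1, rr[j] - mark_half_size):pmin(nrow(g), rr[j] + mark_half_size)
      ci <- pmax(1, cc[j] - mark_half_size):pmin(ncol(g), cc[j] + mark_half_size)
      for (ch in 1:3) rgb[ri, ci, ch] <- col[ch]
      n_marks <- n_marks + 1L
    }
  }
  if (n_marks == 0L) {
    warning("no generators fall in the selected region(s); returning an ",
            "unannotated copy", call. = FALSE)
  }
  rgb
}
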