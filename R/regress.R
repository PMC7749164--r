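#' Univariate screen of topology summaries against a response
#'
#' Fits one ordinary least-squares simple regression per explanatory variable
#' (`response ~ variable`), reporting the slope, its t-value, the two-sided
#' p-value from the t distribution with n - 2 degrees of freedom, and the
#' Benjamini-Hochberg false discovery rate across the screened variables. The
#' default variable set is the study's fourteen: sex, age, temperature,
#' humidity, the component and hole counts, and mean/sd of mid-life and
#' life-time per homology dimension. Zero-variance variables are reported
#' with `NA` statistics and excluded from the FDR adjustment.
#'
#' @param data a tibble such as the output of [cohort_summaries()].
#' @param response response column name (default `"tewl"`; moisture columns
#'   work identically).
#' @param variables explanatory column names (default: the fourteen above,
#'   intersected with `names(data)`).
#' @return a `tewl_screen` tibble with columns `term`, `slope`, `t_value`,
#'   `p_value`, `r_squared`, `fdr`, ordered as given.
#' @export
univariate_screen <- function(data, response = "tewl", variables = NULL) {
  if (is.null(variables)) {
    variables <- intersect(screen_variables(), names(data))
  }
  y <- data[[response]]
  rows <- purrr::map(variables, function(v) {
    x <- data[[v]]
    ok <- complete.cases(x, y)
    xo <- x[ok]; yo <- y[ok]
    if (length(xo) < 3 || sd(xo) == 0) {
      return(tibble::tibble(term = v, slope = NA_real_, t_value = NA_real_,
                            p_value = NA_real_, r_squared = NA_real_))
    }
    f <- lm(yo ~ xo)
    s <- summary(f)
    tibble::tibble(term = v,
                   slope = unname(coef(f)[2]),
                   t_value = s$coefficients[2, "t value"],
                   p_value = s$coefficients[2, "Pr(>|t|)"],
                   r_squared = s$r.squared)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- p.adjust(out$p_value[ok], method = "BH")
  structure(out, class = c("tewl_screen", class(out)), response = response)
}

screen_variables <- function() {
  c("sex", "age", "temperature", "humidity", "n_components", "n_holes",
    "mean_midlife_0", "sd_midlife_0", "mean_lifetime_0", "sd_lifetime_0",
    "mean_midlife_1", "sd_midlife_1", "mean_lifetime_1", "sd_lifetime_1")
}

#' Split a cohort into training and test subjects
#'
#' The split is by subject: every image of a subject falls on the same side,
#' so no subject leaks between training and test.
#'
#' @param data a tibble with a `subject_id` column.
#' @param train_fraction fraction of subjects assigned to training
#'   (default 0.7).
#' @param seed optional seed making the split reproducible.
#' @return a list with character vectors `train` and `test`.
#' @export
split_cohort <- function(data, train_fraction = 0.7, seed = NULL) {
  subjects <- unique(data$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  with_seed(seed, {
    n_train <- min(max(1L, round(train_fraction * length(subjects))),
                   length(subjects) - 1L)
    train <- sample(subjects, n_train)
    list(train = sort(train), test = sort(setdiff(subjects, train)))
  })
}

#' PCA reduction fitted on training features only
#'
#' Centers (and by default standardizes) the training columns, fits principal
#' components, keeps every component whose proportion of variance exceeds
#' `min_ratio` (at least one), and applies the identical projection to the
#' test rows. Standardization is used because persistence-image columns span
#' orders of magnitude. Zero-variance columns are dropped before scaling.
#'
#' @param train,test numeric matrices with identical columns (`test` may be
#'   `NULL`).
#' @param min_ratio minimum contribution ratio (default 0.01).
#' @param scale standardize columns to unit variance (default `TRUE`).
#' @return a list with matrices `train` and `test` (columns `pc_01`, ...),
#'   `rotation`, `center`, `scale`, `kept_features`, and `var_ratio` for the
#'   kept components.
#' @export
pca_reduce <- function(train, test = NULL, min_ratio = 0.01, scale = TRUE) {
  train <- as.matrix(train)
  keep <- apply(train, 2, sd) > 0
  pc <- prcomp(train[, keep, drop = FALSE], center = TRUE, scale. = scale)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- max(1L, sum(ratio > min_ratio))
  project <- function(m) {
    s <- scale(m[, keep, drop = FALSE], pc$center,
               if (isTRUE(scale)) pc$scale else FALSE)
    out <- s %*% pc$rotation[, seq_len(k), drop = FALSE]
    colnames(out) <- sprintf("pc_%02d", seq_len(k))
    out
  }
  list(train = project(train),
       test = if (!is.null(test)) project(as.matrix(test)),
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       center = pc$center,
       scale = if (isTRUE(scale)) pc$scale else NULL,
       kept_features = colnames(train)[keep],
       var_ratio = ratio[seq_len(k)])
}

feature_columns <- function(data) {
  grep("^(pd[01]_|pc_)", names(data), value = TRUE)
}

covariate_columns <- function(data) {
  intersect(c("age", "sex", "temperature", "humidity"), names(data))
}

model_matrix_of <- function(data, features) {
  m <- as.matrix(data[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Train a regression model with subject-level repeated cross-validation
#'
#' Hyperparameters are chosen by mean RMSE over `cv_repeats` separate
#' `cv_folds`-fold cross-validations on the training rows, with folds split
#' by subject so images of one subject never straddle a fold boundary; the
#' winning configuration is refit on all rows. Image features (diagram-region
#' or principal-component columns) are combined with the age, sex,
#' temperature and humidity covariates present in `data`.
#'
#' @param data training feature table: `subject_id`, the response column,
#'   feature columns (`pd*_r*_c*` or `pc_*`) and covariates.
#' @param response response column name.
#' @param algorithm one of the seven learner names (see [fit_learner()]).
#' @param cv_folds,cv_repeats cross-validation layout (defaults 10 and 10).
#' @param grid hyperparameter grid as from [learner_grid()]; `NULL` for the
#'   default grid, `list()` to skip tuning and use defaults.
#' @param seed optional seed covering fold assignment and stochastic fitting.
#' @return a `skintda_model` with the fitted learner, the chosen
#'   hyperparameters and the cross-validation table.
#' @export
train_model <- function(data, response = "tewl", algorithm = "random_forest",
                        cv_folds = 10, cv_repeats = 10, grid = NULL,
                        seed = NULL) {
  features <- c(feature_columns(data), covariate_columns(data))
  if (length(features) == 0) stop("no feature columns found", call. = FALSE)
  x <- model_matrix_of(data, features)
  y <- data[[response]]
  with_seed(seed, {
    if (is.null(grid)) grid <- learner_grid(algorithm, ncol(x))
    combos <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
              else data.frame(row.names = 1)
    cv_table <- NULL
    if (nrow(combos) > 1) {
      subjects <- unique(data$subject_id)
      folds <- min(cv_folds, length(subjects))
      rmse <- matrix(NA_real_, nrow(combos), cv_repeats * folds)
      col <- 0L
      for (rep in seq_len(cv_repeats)) {
        fold_of <- sample(rep_len(seq_len(folds), length(subjects)))
        names(fold_of) <- subjects
        for (f in seq_len(folds)) {
          col <- col + 1L
          hold <- fold_of[data$subject_id] == f
          if (!any(hold) || all(hold)) next
          for (g in seq_len(nrow(combos))) {
            fit <- fit_learner(x[!hold, , drop = FALSE], y[!hold], algorithm,
                               params = as.list(combos[g, , drop = FALSE]))
            pred <- predict(fit, x[hold, , drop = FALSE])
            rmse[g, col] <- sqrt(mean((pred - y[hold])^2))
          }
        }
      }
      mean_rmse <- rowMeans(rmse, na.rm = TRUE)
      best <- which.min(mean_rmse)
      cv_table <- dplyr::bind_cols(tibble::as_tibble(combos),
                                   tibble::tibble(cv_rmse = mean_rmse))
    } else {
      best <- 1L
    }
    best_params <- if (nrow(combos)) as.list(combos[best, , drop = FALSE]) else list()
    learner <- fit_learner(x, y, algorithm, params = best_params)
    structure(list(learner = learner, algorithm = algorithm,
                   response = response, features = features,
                   best_params = best_params, cv = cv_table),
              class = "skintda_model")
  })
}

#' @exportS3Method base::print
print.skintda_model <- function(x, ...) {
  cat(sprintf("<skintda_model: %s -> %s> %d features\n", x$algorithm,
              x$response, length(x$features)))
  if (length(x$best_params)) {
    cat("  params:", paste(names(x$best_params), unlist(x$best_params),
                           sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @param object a `skintda_model`.
#' @param newdata feature table with the training columns.
#' @param ... unused.
#' @rdname train_model
#' @export
predict.skintda_model <- function(object, newdata, ...) {
  predict(object$learner, model_matrix_of(newdata, object$features))
}

#' Subject-level predictions
#'
#' Predicts per image and aggregates to one value per (subject, session) by
#' the median of the image predictions (for an even count, the mean of the
#' two middle values).
#'
#' @param model a [train_model()] result.
#' @param data feature table with `subject_id` and `session` columns.
#' @return a tibble `subject_id`, `session`, `prediction`, plus `observed`
#'   when the response column is present.
#' @export
predict_subject <- function(model, data) {
  data$.pred <- predict(model, data)
  grp <- dplyr::group_by(data, .data$subject_id, .data$session)
  out <- if (model$response %in% names(data)) {
    dplyr::summarise(grp, prediction = median(.data$.pred),
                     observed = .data[[model$response]][1], .groups = "drop")
  } else {
    dplyr::summarise(grp, prediction = median(.data$.pred), .groups = "drop")
  }
  out
}

#' Prediction accuracy metrics
#'
#' @param estimate predicted values.
#' @param truth observed values (same length, >= 2).
#' @return a one-row tibble with `r2` (1 - SSE/SST; `NA` when the
#'   observations have zero variance), `rmse` and `mae`.
#' @export
evaluate_predictions <- function(estimate, truth) {
  if (length(truth) < 2) stop("need at least 2 pairs", call. = FALSE)
  sse <- sum((truth - estimate)^2)
  sst <- sum((truth - mean(truth))^2)
  tibble::tibble(
    r2 = if (sst == 0) NA_real_ else 1 - sse / sst,
    rmse = sqrt(mean((truth - estimate)^2)),
    mae = mean(abs(truth - estimate))
  )
}
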