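test_that("univariate screen reproduces exact fits and the BH step-up", {
  d <- tibble::tibble(tewl = c(2, 4, 6), age = c(1, 2, 3),
                      sex = c(0, 0, 0))
  sc <- suppressWarnings(univariate_screen(d, "tewl", variables = c("age", "sex")))  # perfect fit
  expect_equal(sc$slope[sc$term == "age"], 2)
  expect_equal(sc$r_squared[sc$term == "age"], 1)
  expect_lt(sc$p_value[sc$term == "age"], 1e-6)
  # zero-variance predictor: NA and excluded from FDR
  expect_true(is.na(sc$p_value[sc$term == "sex"]))
  expect_true(is.na(sc$fdr[sc$term == "sex"]))
  expect_equal(sc$fdr[sc$term == "age"], sc$p_value[sc$term == "age"])

  # BH step-up on p = (.01, .02, .03, .04), m = 4 -> all 0.04 (hand formula:
  # cummin over i of p_i * m / i from the largest rank down)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("the screen holds its type-I error rate under the null", {
  set.seed(101)
  n_sim <- 400
  hits <- 0
  for (i in seq_len(n_sim)) {
    d <- tibble::tibble(tewl = rnorm(20), age = rnorm(20))
    sc <- univariate_screen(d, "tewl", variables = "age")
    hits <- hits + (sc$p_value < 0.05)
  }
  expect_gt(hits / n_sim, 0.02)
  expect_lt(hits / n_sim, 0.09)
})

test_that("cohort splits are by subject, sized correctly, and seeded", {
  d <- tibble::tibble(subject_id = rep(sprintf("s%02d", 1:10), each = 3))
  sp <- split_cohort(d, 0.7, seed = 3)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_cohort(d, 0.7, seed = 3))
  expect_false(identical(sp, split_cohort(d, 0.7, seed = 4)))
})

test_that("PCA reduction conserves variance and reconstructs kept components", {
  set.seed(102)
  # two informative directions, several noise columns
  z <- matrix(rnorm(200), 100, 2)
  x <- cbind(z %*% matrix(c(3, 1, 1, -2), 2), matrix(rnorm(400, sd = 0.05),
                                                     100, 4))
  colnames(x) <- paste0("v", 1:6)
  red <- pca_reduce(x, x[1:10, , drop = FALSE], min_ratio = 0.01,
                    scale = FALSE)
  expect_equal(red$test, red$train[1:10, , drop = FALSE])
  # total variance of scores + dropped equals total variance of input
  pc_all <- prcomp(x, center = TRUE, scale. = FALSE)
  expect_equal(sum(apply(red$train, 2, var)),
               sum(pc_all$sdev[seq_len(ncol(red$train))]^2))
  # back-projection loses only dropped-component variance
  recon <- red$train %*% t(red$rotation)
  centred <- scale(x, center = red$center, scale = FALSE)
  lost <- sum((centred - recon)^2) / (nrow(x) - 1)
  expect_equal(lost, sum(pc_all$sdev^2) - sum(pc_all$sdev[seq_len(ncol(red$train))]^2),
               tolerance = 1e-8)
  # degenerate: all variance on one axis -> one component kept
  one <- cbind(rnorm(50), 0.001 * rnorm(50))
  colnames(one) <- c("a", "b")
  expect_equal(ncol(pca_reduce(one, min_ratio = 0.01, scale = FALSE)$train), 1)
})

test_that("subject-median aggregation follows the median conventions", {
  d <- tibble::tibble(subject_id = c("a", "a", "a", "b", "b"),
                      session = 1L,
                      tewl = c(10, 10, 10, 20, 20),
                      pc_01 = c(3, 1, 2, 5, 7))
  model <- train_model(d, "tewl", "linear", grid = list())
  p <- predict_subject(model, d)
  lin <- predict(model, d)
  expect_equal(p$prediction[p$subject_id == "a"], median(lin[1:3]))
  expect_equal(p$prediction[p$subject_id == "b"], mean(lin[4:5]))  # even count
  expect_equal(p$observed, c(10, 20))
})

test_that("metrics match hand arithmetic and obey rmse >= mae", {
  m <- evaluate_predictions(c(2, 2, 2), c(1, 2, 3))
  expect_equal(m$r2, 0)
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$mae, 2 / 3)
  perfect <- evaluate_predictions(1:5, 1:5)
  expect_equal(unlist(perfect), c(r2 = 1, rmse = 0, mae = 0))
  expect_true(is.na(evaluate_predictions(c(1, 2), c(3, 3))$r2))
  set.seed(103)
  for (i in 1:20) {
    obs <- rnorm(10); est <- rnorm(10)
    mm <- evaluate_predictions(est, obs)
    expect_gte(mm$rmse, mm$mae)
    expect_gte(mm$mae, 0)
    expect_lte(mm$r2, 1)
  }
})

test_that("cross-validated training picks sensible hyperparameters deterministically", {
  set.seed(104)
  n_sub <- 12
  d <- tibble::tibble(subject_id = rep(sprintf("s%02d", 1:n_sub), each = 3),
                      session = 1L)
  d$pc_01 <- rnorm(nrow(d))
  d$pc_02 <- rnorm(nrow(d))
  d$tewl <- 3 + 2 * d$pc_01 + rnorm(nrow(d), sd = 0.3)
  m1 <- train_model(d, "tewl", "elastic_net", cv_folds = 4, cv_repeats = 2,
                    seed = 11)
  m2 <- train_model(d, "tewl", "elastic_net", cv_folds = 4, cv_repeats = 2,
                    seed = 11)
  expect_identical(m1$best_params, m2$best_params)
  expect_s3_class(m1$cv, "tbl_df")
  # a linear model on exactly linear data reaches CV RMSE near the noise sd
  lin <- train_model(d, "tewl", "linear")
  pred <- predict(lin, d)
  expect_lt(sqrt(mean((pred - d$tewl)^2)), 0.45)
  expect_error(train_model(d, "tewl", "nonsense"), "unknown|arg")
})
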