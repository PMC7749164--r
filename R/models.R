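#' Regression learners
#'
#' A unified fit/predict surface over the seven regression algorithms used in
#' the TEWL prediction benchmark: `random_forest` (bagged CART trees with
#' impurity importance), `svm_rbf` (epsilon-SVR with a Gaussian kernel, solved
#' as a quadratic program), `elastic_net` (via glmnet), `gb_linear`
#' (componentwise linear L2 boosting), `gb_tree` (gradient-boosted CART),
#' `neural_net` (one hidden tanh layer with weight decay, BFGS-trained), and
#' `linear` (ordinary least squares). Tree learners and the neural net draw
#' randomness from R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param x numeric feature matrix (rows = observations).
#' @param y numeric response.
#' @param algorithm one of the seven names above.
#' @param params named list of hyperparameters; missing entries take the
#'   defaults in [learner_grid()].
#' @return a `skintda_learner`.
#' @export
fit_learner <- function(x, y,
                        algorithm = c("random_forest", "svm_rbf", "elastic_net",
                                      "gb_linear", "gb_tree", "neural_net",
                                      "linear"),
                        params = list()) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  defaults <- lapply(learner_grid(algorithm, p), `[[`, 1)
  params <- utils::modifyList(defaults, params)
  fit <- switch(algorithm,
    linear = fit_linear(x, y),
    elastic_net = glmnet::glmnet(x, y, alpha = params$alpha,
                                 lambda = params$lambda),
    random_forest = cpp_forest_fit(x, y, params$ntree,
                                   max(1L, min(p, as.integer(params$mtry))),
                                   params$min_node, params$max_depth),
    gb_tree = fit_gb_tree(x, y, params),
    gb_linear = fit_gb_linear(x, y, params),
    svm_rbf = fit_svr(x, y, params),
    neural_net = fit_mlp(x, y, params)
  )
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 features = colnames(x)),
            class = "skintda_learner")
}

#' @exportS3Method base::print
print.skintda_learner <- function(x, ...) {
  cat(sprintf("<skintda_learner: %s> %d features\n", x$algorithm,
              length(x$features)))
  invisible(x)
}

#' @param object a `skintda_learner`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @rdname fit_learner
#' @export
predict.skintda_learner <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  switch(object$algorithm,
    linear = drop(cbind(1, x) %*% object$fit$coef),
    elastic_net = drop(predict(object$fit, newx = x,
                               s = object$params$lambda)),
    random_forest = cpp_trees_predict(object$fit$trees, x),
    gb_tree = predict_gb_tree(object$fit, x),
    gb_linear = predict_gb_linear(object$fit, x),
    svm_rbf = predict_svr(object$fit, x),
    neural_net = predict_mlp(object$fit, x)
  )
}

#' Per-feature importance of a fitted learner
#'
#' Impurity-based importance (total reduction of the squared-error criterion
#' attributable to splits on each feature) for the tree learners. Other
#' algorithms have no impurity notion and raise an error pointing to
#' permutation importance, which is out of scope here.
#'
#' @param learner a [fit_learner()] result.
#' @return named numeric vector (not normalized).
#' @export
learner_importance <- function(learner) {
  if (!learner$algorithm %in% c("random_forest", "gb_tree")) {
    stop("impurity importance is only defined for tree models ",
         "(random_forest, gb_tree); use permutation importance instead ",
         "(not provided)", call. = FALSE)
  }
  imp <- learner$fit$importance
  setNames(as.numeric(imp), learner$features)
}

#' Hyperparameter grids
#'
#' Small fixed grids standing in for the tuning defaults of the usual
#' machine-learning frameworks (which the study inherits but does not print).
#' The first value of each parameter is the fitting default.
#'
#' @param algorithm learner name.
#' @param p number of features.
#' @return named list of candidate values per hyperparameter.
#' @export
learner_grid <- function(algorithm, p) {
  switch(algorithm,
    linear = list(),
    elastic_net = list(alpha = c(0.5, 0.1, 0.9),
                       lambda = c(0.1, 0.01, 1)),
    random_forest = list(mtry = unique(pmax(1, c(floor(p / 3),
                                                 floor(sqrt(p)),
                                                 floor(p / 2)))),
                         ntree = 300L, min_node = 5L, max_depth = 25L),
    gb_tree = list(max_depth = c(3L, 2L), nrounds = 100L, eta = 0.1,
                   min_node = 10L),
    gb_linear = list(nrounds = c(100L, 250L), eta = 0.1),
    svm_rbf = list(cost = c(1, 10), gamma = 1 / max(p, 1), epsilon = 0.1),
    neural_net = list(size = c(5L, 3L), decay = c(0.1, 0.01), maxit = 200L),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

# ---- engines ---------------------------------------------------------------

fit_linear <- function(x, y) {
  f <- stats::lm.fit(cbind(1, x), y)
  co <- f$coefficients
  co[is.na(co)] <- 0
  list(coef = co)
}

fit_gb_tree <- function(x, y, params) {
  n <- nrow(x)
  f0 <- mean(y)
  pred <- rep(f0, n)
  trees <- vector("list", params$nrounds)
  imp <- numeric(ncol(x))
  rows <- 0:(n - 1L)
  for (m in seq_len(params$nrounds)) {
    res <- y - pred
    tr <- cpp_tree_fit(x, res, rows, ncol(x), params$min_node, params$max_depth)
    trees[[m]] <- tr$tree
    imp <- imp + tr$importance
    pred <- pred + params$eta * cpp_tree_predict(tr$tree, x)
  }
  list(f0 = f0, trees = trees, eta = params$eta, importance = imp)
}

predict_gb_tree <- function(fit, x) {
  out <- rep(fit$f0, nrow(x))
  for (tr in fit$trees) out <- out + fit$eta * cpp_tree_predict(tr, x)
  out
}

fit_gb_linear <- function(x, y, params) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  beta <- numeric(ncol(x))
  intercept <- mean(y)
  res <- y - intercept
  for (m in seq_len(params$nrounds)) {
    cors <- drop(crossprod(xs, res)) / nrow(x)
    j <- which.max(abs(cors))
    b <- cors[j] / mean(xs[, j]^2)
    beta[j] <- beta[j] + params$eta * b
    res <- res - params$eta * b * xs[, j]
  }
  list(intercept = intercept, beta = beta, center = ctr, scale = scl)
}

predict_gb_linear <- function(fit, x) {
  xs <- scale(x, fit$center, fit$scale)
  drop(fit$intercept + xs %*% fit$beta)
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  exp(-gamma * pmax(outer(an, bn, "+") - 2 * tcrossprod(a, b), 0))
}

# epsilon-SVR solved through its dual quadratic program (variables alpha and
# alpha*), equality constraint sum(alpha - alpha*) = 0, box [0, C]
fit_svr <- function(x, y, params) {
  ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  yc <- mean(y); ys <- sd(y); if (ys == 0) ys <- 1
  yn <- (y - yc) / ys
  n <- nrow(xs)
  K <- rbf_kernel(xs, xs, params$gamma)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-7, 2 * n)
  dvec <- c(yn - params$epsilon, -yn - params$epsilon)
  Amat <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  bvec <- c(0, rep(0, 2 * n), rep(-params$cost, 2 * n))
  sol <- quadprog::solve.QP(D, dvec, Amat, bvec, meq = 1)
  beta <- sol$solution[1:n] - sol$solution[(n + 1):(2 * n)]
  # intercept from non-bound support vectors, robust fallback to the median
  fx <- drop(K %*% beta)
  a1 <- sol$solution[1:n]; a2 <- sol$solution[(n + 1):(2 * n)]
  tol <- 1e-6 * params$cost
  free1 <- a1 > tol & a1 < params$cost - tol
  free2 <- a2 > tol & a2 < params$cost - tol
  b <- if (any(free1) || any(free2)) {
    mean(c((yn - fx - params$epsilon)[free1], (yn - fx + params$epsilon)[free2]))
  } else {
    median(yn - fx)
  }
  list(beta = beta, b = b, sv = xs, gamma = params$gamma,
       center = ctr, scale = scl, y_center = yc, y_scale = ys)
}

predict_svr <- function(fit, x) {
  xs <- scale(x, fit$center, fit$scale)
  K <- rbf_kernel(xs, fit$sv, fit$gamma)
  drop(K %*% fit$beta + fit$b) * fit$y_scale + fit$y_center
}

# single hidden tanh layer, squared loss + L2 weight decay, BFGS with
# analytic gradients on standardized inputs and response
fit_mlp <- function(x, y, params) {
  ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  yc <- mean(y); ys <- sd(y); if (ys == 0) ys <- 1
  yn <- (y - yc) / ys
  p <- ncol(xs); h <- params$size; n <- nrow(xs)
  n_w1 <- (p + 1) * h
  unpack <- function(w) {
    list(W1 = matrix(w[1:n_w1], p + 1, h),
         W2 = w[(n_w1 + 1):(n_w1 + h + 1)])
  }
  xb <- cbind(1, xs)
  obj <- function(w) {
    wl <- unpack(w)
    A <- tanh(xb %*% wl$W1)
    out <- drop(cbind(1, A) %*% wl$W2)
    mean((out - yn)^2) + params$decay * sum(w^2)
  }
  grad <- function(w) {
    wl <- unpack(w)
    Z <- xb %*% wl$W1
    A <- tanh(Z)
    out <- drop(cbind(1, A) %*% wl$W2)
    e <- 2 * (out - yn) / n
    gW2 <- drop(crossprod(cbind(1, A), e))
    dA <- outer(e, wl$W2[-1]) * (1 - A^2)
    gW1 <- crossprod(xb, dA)
    c(as.vector(gW1), gW2) + 2 * params$decay * w
  }
  w0 <- runif(n_w1 + h + 1, -0.5, 0.5)
  opt <- optim(w0, obj, grad, method = "BFGS",
               control = list(maxit = params$maxit))
  c(unpack(opt$par),
    list(center = ctr, scale = scl, y_center = yc, y_scale = ys))
}

predict_mlp <- function(fit, x) {
  xs <- scale(x, fit$center, fit$scale)
  A <- tanh(cbind(1, xs) %*% fit$W1)
  drop(cbind(1, A) %*% fit$W2) * fit$y_scale + fit$y_center
}
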