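# Regression algorithm registry.
#
# Each entry provides fit(X, y, seed) -> model and predict(model, X) -> numeric,
# with X a numeric matrix (rows = pairs, columns = features). Hyperparameters
# are fixed registry defaults; there is no nested tuning.

.standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv,
       apply = function(Z) sweep(sweep(Z, 2, mu), 2, sdv, "/"))
}

.fit_ranger <- function(X, y, seed, splitrule, mtry, importance = "none",
                        num_trees = 100) {
  args <- list(
    x = X, y = y, num.trees = num_trees,
    mtry = max(1L, mtry), min.node.size = 10,
    splitrule = splitrule, seed = seed, num.threads = 1,
    importance = importance, verbose = FALSE
  )
  if (splitrule == "extratrees") {
    args$num.random.splits <- 1
    args$replace <- FALSE
    args$sample.fraction <- 1
  }
  do.call(ranger::ranger, args)
}

#' Registry of regression algorithms
#'
#' The model roster evaluated for position-selectivity regression:
#' extremely randomized trees (`extra_trees`), random forest
#' (`random_forest`), gradient-boosted trees (`gradient_boosting`),
#' epsilon-support-vector regression with an RBF kernel (`svr`),
#' k-nearest-neighbors (`knn`, k = 5 on standardized features), closed-form
#' ridge regression (`ridge`, lambda = 1e-6 so the unpenalized limit is
#' numerically ordinary least squares) and ordinary linear regression
#' (`linear`). Tree ensembles use 100 trees (300 for random forest) with a
#' minimum node size of 5; extra-trees draws one random split per candidate
#' feature over all features, without bootstrapping, and random forest uses
#' variance splits on bootstrapped samples with mtry = p/3. All fits are
#' single-threaded and seeded, hence deterministic.
#'
#' @return A named list; each element has `label`, `fit(X, y, seed)`,
#'   `predict(model, X)` and a logical `tree_based` (impurity importances
#'   available).
#' @export
model_registry <- function() {
  list(
    extra_trees = list(
      label = "Extra-Trees",
      tree_based = TRUE,
      fit = function(X, y, seed) {
        .fit_ranger(X, y, seed, "extratrees", mtry = ncol(X))
      },
      predict = function(model, X) {
        stats::predict(model, data = X, num.threads = 1)$predictions
      }
    ),
    random_forest = list(
      label = "Random Forest",
      tree_based = TRUE,
      fit = function(X, y, seed) {
        .fit_ranger(X, y, seed, "variance", mtry = floor(ncol(X) / 3),
                    num_trees = 300)
      },
      predict = function(model, X) {
        stats::predict(model, data = X, num.threads = 1)$predictions
      }
    ),
    gradient_boosting = list(
      label = "Gradient Boosting",
      tree_based = TRUE,
      fit = function(X, y, seed) {
        set.seed(seed)
        xgboost::xgboost(x = X, y = y, nrounds = 300, max_depth = 3,
                         learning_rate = 0.05, nthreads = 1, verbosity = 0,
                         seed = seed)
      },
      predict = function(model, X) as.numeric(stats::predict(model, X))
    ),
    svr = list(
      label = "Support-Vector Regression",
      tree_based = FALSE,
      fit = function(X, y, seed) {
        set.seed(seed)
        std <- .standardizer(X)
        list(std = std,
             svm = e1071::svm(x = std$apply(X), y = y,
                              type = "eps-regression", kernel = "radial",
                              scale = FALSE))
      },
      predict = function(model, X) {
        as.numeric(stats::predict(model$svm, model$std$apply(X)))
      }
    ),
    knn = list(
      label = "k-Nearest Neighbors",
      tree_based = FALSE,
      fit = function(X, y, seed) {
        std <- .standardizer(X)
        list(std = std,
             knn = caret::knnreg(std$apply(X), y,
                                 k = min(5L, max(1L, nrow(X) - 1L))))
      },
      predict = function(model, X) {
        as.numeric(stats::predict(model$knn, model$std$apply(X)))
      }
    ),
    ridge = list(
      label = "Ridge Regression",
      tree_based = FALSE,
      fit = function(X, y, seed) .fit_ridge(X, y, lambda = 1e-6),
      predict = function(model, X) .predict_ridge(model, X)
    ),
    linear = list(
      label = "Linear Regression",
      tree_based = FALSE,
      fit = function(X, y, seed) .fit_ridge(X, y, lambda = 0),
      predict = function(model, X) .predict_ridge(model, X)
    )
  )
}

# Closed-form (regularized) least squares on centered data. lambda = 0 gives
# minimum-norm OLS via the pseudoinverse, so collinear features are safe.
.fit_ridge <- function(X, y, lambda = 1e-6) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ybar <- mean(y)
  if (lambda > 0) {
    K <- crossprod(Xc) + diag(lambda, ncol(Xc))
    beta <- solve(K, crossprod(Xc, y - ybar))
  } else {
    sv <- svd(Xc)
    keep <- sv$d > max(sv$d[1], 1) * 1e-10
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], y - ybar)) / sv$d[keep])
  }
  list(mu = mu, ybar = ybar, beta = drop(beta))
}

.predict_ridge <- function(model, X) {
  drop(sweep(X, 2, model$mu) %*% model$beta) + model$ybar
}

#' Fit one registry algorithm
#'
#' @param algorithm Registry name (see [model_registry()]).
#' @param X Numeric feature matrix.
#' @param y Numeric target vector.
#' @param seed Integer seed controlling all fit randomness.
#' @return A fitted model object of class `regiosel_model` wrapping the
#'   registry entry and fit.
#' @export
fit_model <- function(algorithm, X, y, seed = 1) {
  reg <- model_registry()
  if (!algorithm %in% names(reg)) {
    stop("unknown algorithm '", algorithm, "'; registry has: ",
         paste(names(reg), collapse = ", "))
  }
  entry <- reg[[algorithm]]
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  set.seed(seed)
  structure(list(algorithm = algorithm, entry = entry,
                 model = entry$fit(X, y, seed),
                 features = colnames(X), seed = seed),
            class = "regiosel_model")
}

#' @export
predict.regiosel_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  object$entry$predict(object$model, X)
}

#' Save or load a fitted model archive
#'
#' The archive records the package version, the fitted model, its feature
#' schema and a hash of that schema. `load_model()` refuses to return a
#' model whose stored schema hash does not match its own features, and
#' `predict()`ing with a mismatched feature set fails by construction.
#'
#' @param object A `regiosel_model` from [fit_model()].
#' @param path Archive path (`.rds`).
#' @return `save_model()`: `path`, invisibly. `load_model()`: the restored
#'   `regiosel_model`.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "regiosel_model"))
  archive <- list(version = as.character(utils::packageVersion("regiosel")),
                  model = object,
                  schema_hash = rlang::hash(object$features))
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  archive <- readRDS(path)
  if (!identical(archive$schema_hash, rlang::hash(archive$model$features))) {
    stop("model archive schema hash mismatch; refusing to predict with it")
  }
  archive$model
}
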